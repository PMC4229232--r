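# Ensemble bands and correlation analysis.

test_that("two constant trials give textbook two-point statistics", {
  npts <- 101
  nms <- contact_output_names(npts)
  trace <- rbind(rep(1, length(nms)), rep(3, length(nms)))
  ens <- make_fake_ensemble(trace, matrix(stats::rnorm(4), 2, 2,
                                          dimnames = list(NULL, c("a", "b"))))
  ens$output_names <- nms
  colnames(ens$trace) <- nms
  b <- ensemble_bands(ens)
  expect_equal(unique(b$bands$mean), 2)
  expect_equal(unique(b$bands$sd), sqrt(2))
  expect_equal(unique(b$bands$range), 2)
  # identical trials: zero spread
  ens$trace[2, ] <- 1
  b2 <- ensemble_bands(ens)
  expect_equal(unique(b2$bands$sd), 0)
  expect_equal(unique(b2$bands$range), 0)
})

test_that("bands agree with direct column-wise statistics", {
  set.seed(71)
  npts <- 101
  nms <- contact_output_names(npts)
  trace <- matrix(stats::rnorm(100 * length(nms), 2, 0.4), 100)
  colnames(trace) <- nms
  ens <- make_fake_ensemble(trace, matrix(stats::rnorm(200), 100, 2,
                                          dimnames = list(NULL, c("a", "b"))))
  b <- ensemble_bands(ens)
  expect_equal(b$bands$mean, unname(colMeans(trace)), tolerance = 1e-12)
  expect_equal(b$bands$sd, unname(apply(trace, 2, stats::sd)), tolerance = 1e-12)
  expect_equal(b$bands$range,
               unname(apply(trace, 2, max) - apply(trace, 2, min)),
               tolerance = 1e-12)
  expect_equal(max(b$summary$max_sd), max(b$bands$sd), tolerance = 1e-12)
  # aggregates respect max >= mean
  expect_true(all(b$summary$max_sd >= b$summary$mean_sd))
})

test_that("an exact linear dependence gives R2 = 1 at every frame", {
  set.seed(72)
  npts <- 11
  nms <- contact_output_names(npts)
  n <- 40
  x <- stats::rnorm(n)
  X <- cbind(x1 = x, x2 = stats::rnorm(n), x3 = rep(2, n))  # x3 degenerate
  trace <- matrix(0, n, length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) trace[, j] <- 2 + 3 * x
  ens <- make_fake_ensemble(trace, X)
  rep_ <- correlate(ens)
  expect_equal(unname(rep_$r2["x1", ]), rep(1, length(nms)), tolerance = 1e-12)
  expect_true(all(rep_$p["x1", ] < 1e-10))
  # degenerate input is masked, never significant
  expect_true(all(rep_$masked["x3", ]))
  expect_true(all(is.na(rep_$r2["x3", ])))
})

test_that("R2 equals the squared Pearson correlation and the regression R2", {
  set.seed(73)
  n <- 60
  x <- stats::rnorm(n)
  y <- 1 + 0.5 * x + stats::rnorm(n, 0, 0.7)
  npts <- 2
  nms <- contact_output_names(npts)
  trace <- matrix(y, n, length(nms), dimnames = list(NULL, nms))
  ens <- make_fake_ensemble(trace, cbind(x1 = x))
  rep_ <- correlate(ens)
  lmfit <- summary(stats::lm(y ~ x))
  expect_equal(unname(rep_$r2["x1", 1]), lmfit$r.squared, tolerance = 1e-12)
  expect_equal(unname(rep_$r2["x1", 1]), stats::cor(x, y)^2, tolerance = 1e-12)
  expect_equal(unname(rep_$p["x1", 1]), lmfit$coefficients["x", 4],
               tolerance = 1e-10)
})

test_that("observed R2 under known population correlation falls in the Fisher-z interval", {
  set.seed(74)
  n <- 500; rho <- 0.6
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  npts <- 2
  nms <- contact_output_names(npts)
  trace <- matrix(y, n, length(nms), dimnames = list(NULL, nms))
  ens <- make_fake_ensemble(trace, cbind(x1 = x))
  r2 <- unname(correlate(ens)$r2["x1", 1])
  z <- atanh(rho); se <- 1 / sqrt(n - 3)
  bounds <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)^2
  expect_gt(r2, bounds[1]); expect_lt(r2, bounds[2])
})

test_that("significance summary matches a brute-force recount", {
  set.seed(75)
  npts <- 101
  nms <- contact_output_names(npts)
  n <- 50; nv <- 20
  X <- matrix(stats::rnorm(n * nv), n, nv,
              dimnames = list(NULL, paste0("v", 1:nv)))
  trace <- matrix(stats::rnorm(n * length(nms)), n,
                  dimnames = list(NULL, nms))
  trace[, 5] <- 3 * X[, 7] + stats::rnorm(n, 0, 0.5)
  ens <- make_fake_ensemble(trace, X)
  rep_ <- correlate(ens)
  s <- significance_summary(rep_)
  sig <- !rep_$masked & rep_$p < 0.001
  expect_equal(s$frac_cells_significant, sum(sig) / sum(!rep_$masked))
  expect_equal(s$frac_cells_above_lo,
               sum(sig & rep_$r2 > 0.2, na.rm = TRUE) / sum(!rep_$masked))
  expect_true("v7" %in% s$involved_inputs)
  # empty case
  rep0 <- rep_
  rep0$p[] <- 0.5
  s0 <- significance_summary(rep0)
  expect_equal(s0$frac_cells_significant, 0)
  expect_length(s0$involved_inputs, 0)
  # counting example: 63 of 1000 cells -> 6.3%
  repc <- list(masked = matrix(FALSE, 10, 100),
               p = matrix(1, 10, 100), r2 = matrix(0.1, 10, 100),
               inputs = paste0("i", 1:10))
  repc$p[sample(1000, 63)] <- 1e-6
  class(repc) <- "msk_correlation"
  expect_equal(significance_summary(repc)$frac_cells_significant, 0.063)
})

test_that("null inputs produce the nominal significant fraction", {
  set.seed(76)
  n <- 100; nv <- 350
  npts <- 101
  nms <- contact_output_names(npts)
  X <- matrix(stats::rnorm(n * nv), n, nv,
              dimnames = list(NULL, paste0("v", 1:nv)))
  trace <- matrix(stats::rnorm(n * length(nms)), n,
                  dimnames = list(NULL, nms))
  ens <- make_fake_ensemble(trace, X)
  rep_ <- correlate(ens)
  s <- significance_summary(rep_)
  ncell <- s$n_cells
  expect_gte(ncell, 1e5)
  ci <- stats::qbinom(c(0.005, 0.995), ncell, 0.001) / ncell
  expect_gte(s$frac_cells_significant, ci[1])
  expect_lte(s$frac_cells_significant, ci[2])
})

test_that("an injected linear dependence is recovered as the top input", {
  set.seed(77)
  n <- 80; nv <- 30
  npts <- 101
  nms <- contact_output_names(npts)
  X <- matrix(stats::rnorm(n * nv), n, nv,
              dimnames = list(NULL, c(paste0("mtu:v", 1:(nv - 1)), "sigma")))
  trace <- matrix(stats::rnorm(n * length(nms), 3, 0.1), n,
                  dimnames = list(NULL, nms))
  inj_frames <- 30:45
  hip_cols <- grep("contact_hip_r", nms)[inj_frames]
  for (j in hip_cols) trace[, j] <- 3 + 0.5 * X[, "mtu:v4"] +
      stats::rnorm(n, 0, 0.05)
  ens <- make_fake_ensemble(trace, X)
  rep_ <- correlate(ens)
  for (j in hip_cols) {
    top <- which.max(rep_$r2[, j])
    expect_equal(rep_$inputs[top], "mtu:v4")
    expect_lt(rep_$p[top, j], 0.001)
  }
})

test_that("tidy and glance return the documented tibbles", {
  set.seed(78)
  npts <- 101
  nms <- c(contact_output_names(npts),
           paste0("muscle:sol:", 1:npts), paste0("angle:hip:", 1:npts),
           paste0("moment:hip:", 1:npts))
  trace <- matrix(stats::rnorm(20 * length(nms), 1, 0.2), 20,
                  dimnames = list(NULL, nms))
  ens <- make_fake_ensemble(trace, matrix(stats::rnorm(40), 20,
                                          dimnames = list(NULL, c("a", "b"))))
  td <- tidy(ens)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("group", "output", "pct", "mean", "sd", "range") %in%
                    names(td)))
  g <- glance(ens)
  expect_equal(nrow(g), 1)
  expect_true(g$max_sd_contact_bw > 0)
  p <- ggplot2::autoplot(ensemble_bands(ens))
  expect_s3_class(p, "ggplot")
})
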