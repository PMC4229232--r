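# Stochastic variables, attachment frames, LHS sampling, instantiation.

test_that("exact plane and line point sets are classified with exact bases", {
  pts <- cbind(stats::runif(12, -1, 1), stats::runif(12, -1, 1), 0)
  fr <- fit_attachment_frame(pts)
  expect_equal(fr$mode, "plane")
  expect_equal(abs(fr$normal), c(0, 0, 1), tolerance = 1e-12)
  lin <- cbind(seq(-1, 1, length.out = 8), 0, 0)
  fr2 <- fit_attachment_frame(lin)
  expect_equal(fr2$mode, "line")
  expect_equal(abs(fr2$basis[, 1]), c(1, 0, 0), tolerance = 1e-12)
  expect_error(fit_attachment_frame(matrix(1, 5, 3)),
               "mskuq_degenerate_attachment")
})

test_that("anisotropic clouds match the eigen-decomposition oracle", {
  set.seed(10)
  A <- rot_axis_angle_test(c(2, -1, 1), 0.9)
  pts <- t(A %*% t(cbind(stats::rnorm(400, 0, 10), stats::rnorm(400, 0, 2),
                         stats::rnorm(400, 0, 0.5))))
  fr <- fit_attachment_frame(pts)
  S <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  eg <- eigen(S, symmetric = TRUE)
  expect_equal(fr$mode, "line")  # 10:2 ratio exceeds the 3.0 threshold
  expect_lt(min(abs(sum(fr$basis[, 1] * eg$vectors[, 1]))), 1 + 1e-8)
  expect_gt(abs(sum(fr$basis[, 1] * eg$vectors[, 1])), 1 - 1e-8)
  fr2 <- fit_attachment_frame(pts, lw_ratio_threshold = 10)
  expect_equal(fr2$mode, "plane")
  expect_gt(abs(sum(fr2$normal * eg$vectors[, 3])), 1 - 1e-8)
})

test_that("variable counting follows the category rules", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  # 3 variables per landmark
  n_lm <- nrow(m$definition$landmarks)
  expect_equal(sum(vars$category == "landmark"), 3 * n_lm)
  expect_equal(sum(vars$category == "sigma"), 1)
  # per-MTU counting rule: 2 per plane-mode origin/insertion, 1 per
  # line-mode, 3 per pseudo point
  mv <- vars[vars$category == "mtu_point" & vars$mtu == "vasmed_r", ]
  expect_equal(nrow(mv), 2 + 2 + 3)  # plane origin + plane insertion + pseudo
  sv <- vars[vars$category == "mtu_point" & vars$mtu == "soleus_r", ]
  expect_equal(nrow(sv), 1 + 1)      # elongated areas -> line mode both ends
  # left-side landmark SDs mirror the right side
  rx <- vars$sd[vars$id == "lm:RGT:x"]
  lx <- vars$sd[vars$id == "lm:LGT:x"]
  expect_equal(rx, lx)
})

test_that("a missing SD entry raises a named error", {
  m <- template_model_cached()
  tab <- landmark_sd_table()
  expect_error(suppressMessages(
    define_stochastic_variables(m, tab[tab$landmark != "RGT", ])),
    "mskuq_missing_sd")
})

test_that("LHS places exactly one draw per probability stratum", {
  vars <- tibble::tibble(
    id = c("u", "n", "n0"), category = "landmark",
    dist = c("uniform", "normal", "normal"),
    mean = c(NA, 3, 5), sd = c(NA, 2, 0), lo = c(0, NA, NA), hi = c(1, NA, NA))
  for (N in c(10, 100)) {
    s <- lhs_sample(vars, N, seed = 9)
    u <- s$values[, "u"]
    expect_equal(sort(floor(u * N)), 0:(N - 1))  # one per [k/N,(k+1)/N)
    pn <- stats::pnorm(s$values[, "n"], 3, 2)
    expect_equal(sort(floor(pn * N)), 0:(N - 1))
    expect_equal(s$values[, "n0"], rep(5, N))     # degenerate distribution
  }
  # moments of a standard-normal column at N = 500
  vars2 <- tibble::tibble(id = "z", category = "landmark", dist = "normal",
                          mean = 0, sd = 1, lo = NA_real_, hi = NA_real_)
  z <- lhs_sample(vars2, 500, seed = 3)$values[, 1]
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(stats::sd(z), 0.9); expect_lt(stats::sd(z), 1.1)
  # determinism
  expect_identical(lhs_sample(vars, 50, seed = 4)$values,
                   lhs_sample(vars, 50, seed = 4)$values)
})

test_that("the zero sample row reproduces the baseline model", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  row <- stats::setNames(rep(0, nrow(vars)), vars$id)
  row["sigma"] <- m$sigma
  m2 <- instantiate_model(m, vars, row)
  expect_equal(m2$definition$landmarks$x, m$definition$landmarks$x,
               tolerance = 1e-12)
  for (nm in names(m$mtus)) {
    expect_equal(m2$mtus[[nm]]$Fmax, m$mtus[[nm]]$Fmax, tolerance = 1e-12)
  }
  expect_equal(m2$segments$thigh_r$inertia, m$segments$thigh_r$inertia,
               tolerance = 1e-12)
})

test_that("doubling sigma exactly doubles every Fmax", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  row <- stats::setNames(rep(0, nrow(vars)), vars$id)
  row["sigma"] <- 122
  m2 <- instantiate_model(m, vars, row)
  f1 <- vapply(m$mtus, `[[`, numeric(1), "Fmax")
  f2 <- vapply(m2$mtus, `[[`, numeric(1), "Fmax")
  expect_equal(unname(f2), unname(2 * f1), tolerance = 1e-12)
})

test_that("plane-constrained points stay in their constraint subspace", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  s <- lhs_sample(vars, 40, seed = 12)
  plane_vars <- vars[grepl(":plane1$", vars$id), ]
  for (i in c(1, 20, 40)) {
    def2 <- mskuq:::perturb_definition(m, vars, s$values[i, ])
    for (k in seq_len(nrow(plane_vars))) {
      v <- plane_vars[k, ]
      mi <- which(vapply(m$definition$mtus, `[[`, "", "name") == v$mtu)
      p0 <- m$definition$mtus[[mi]]$path[[v$point_index]]$pos
      p1 <- def2$mtus[[mi]]$path[[v$point_index]]$pos
      cloud <- m$definition$mtus[[mi]]$attachments[[as.character(v$point_index)]]
      fr <- fit_attachment_frame(cloud)
      disp <- p1 - p0
      # re-projection oracle: displacement has no out-of-plane component
      expect_lt(abs(sum(disp * fr$normal)), 1e-12)
    }
  }
})

test_that("via-point displacement equals the drawn body-axis offsets", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  s <- lhs_sample(vars, 5, seed = 13)
  def2 <- mskuq:::perturb_definition(m, vars, s$values[2, ])
  pv <- vars[vars$category == "mtu_point" & vars$mtu == "tibant_r" &
               !is.na(vars$axis), ]
  mi <- which(vapply(m$definition$mtus, `[[`, "", "name") == "tibant_r")
  p <- unique(pv$point_index)
  disp <- def2$mtus[[mi]]$path[[p]]$pos - m$definition$mtus[[mi]]$path[[p]]$pos
  R0 <- m$segments$shank_r$frame0$R
  expected <- R0 %*% s$values[2, pv$id]
  expect_equal(disp, as.vector(expected), tolerance = 1e-12)
})

test_that("empirical landmark-coordinate SDs match their nominal values", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  s <- lhs_sample(vars, 500, seed = 21)
  lmv <- vars$category == "landmark" & vars$sd > 0
  emp <- apply(s$values[, lmv, drop = FALSE], 2, stats::sd)
  nominal <- vars$sd[lmv]
  expect_lt(max(abs(emp / nominal - 1)), 0.15)
})

test_that("instantiation is deterministic and side-effect free", {
  m <- template_model_cached()
  vars <- template_vars_cached()
  s <- lhs_sample(vars, 3, seed = 31)
  before <- m$definition$landmarks
  m1 <- instantiate_model(m, vars, s$values[1, ])
  m1b <- instantiate_model(m, vars, s$values[1, ])
  expect_equal(m1$definition, m1b$definition, tolerance = 0)
  expect_identical(m$definition$landmarks, before)
})
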