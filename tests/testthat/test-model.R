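# Model compilation, forward kinematics, musculotendon lengths, Fmax.

test_that("neutral pose reproduces the calibration landmark cloud", {
  m <- template_model_cached()
  fp <- forward_position(m, neutral_q(m))
  lm <- m$definition$landmarks
  ord <- match(fp$landmarks$name, lm$name)
  expect_lt(max(abs(fp$landmarks$x - lm$x[ord])), 1e-12)
  expect_lt(max(abs(fp$landmarks$y - lm$y[ord])), 1e-12)
  expect_lt(max(abs(fp$landmarks$z - lm$z[ord])), 1e-12)
})

test_that("pure pelvis translation transports every point equally", {
  m <- template_model_cached()
  q <- neutral_q(m)
  q[c("pelvis_tx", "pelvis_ty", "pelvis_tz")] <- c(0.3, -0.1, 0.05)
  fp0 <- forward_position(m, neutral_q(m))
  fp1 <- forward_position(m, q)
  expect_lt(max(abs(fp1$landmarks$x - fp0$landmarks$x - 0.3)), 1e-12)
  expect_lt(max(abs(fp1$landmarks$y - fp0$landmarks$y + 0.1)), 1e-12)
  expect_lt(max(abs(fp1$landmarks$z - fp0$landmarks$z - 0.05)), 1e-12)
})

test_that("random configurations preserve within-segment distances", {
  m <- template_model_cached()
  set.seed(11)
  for (rep in 1:10) {
    q <- neutral_q(m) + stats::rnorm(length(neutral_q(m)), 0, 0.3)
    fp <- forward_position(m, q)
    fp0 <- forward_position(m, neutral_q(m))
    for (seg in unique(fp$landmarks$segment)) {
      a <- as.matrix(fp$landmarks[fp$landmarks$segment == seg, c("x", "y", "z")])
      b <- as.matrix(fp0$landmarks[fp0$landmarks$segment == seg, c("x", "y", "z")])
      expect_lt(max(abs(dist(a) - dist(b))), 1e-12)
    }
  }
})

test_that("musculotendon length is the direct sum of segment distances", {
  m <- template_model_cached()
  set.seed(12)
  for (rep in 1:10) {
    q <- neutral_q(m) + stats::rnorm(length(neutral_q(m)), 0, 0.2)
    fp <- forward_position(m, q)
    for (mtu in c("recfem_r", "gasmed_l", "tibant_r")) {
      pp <- fp$path_points[fp$path_points$mtu == mtu, ]
      pp <- pp[order(pp$index), ]
      P <- as.matrix(pp[, c("x", "y", "z")])
      oracle <- sum(sqrt(rowSums(diff(P)^2)))
      expect_equal(mtu_length(m, q, mtu), oracle, tolerance = 1e-12)
      # never shorter than the straight origin-insertion line
      expect_gte(mtu_length(m, q, mtu) + 1e-12,
                 sqrt(sum((P[nrow(P), ] - P[1, ])^2)))
    }
  }
})

test_that("a via point coincident with an existing point leaves length unchanged", {
  m <- template_model_cached()
  mtu <- m$mtus$soleus_r
  L0 <- mtu_length(m, neutral_q(m), mtu)
  mtu2 <- mtu
  mtu2$path <- append(mtu2$path, mtu2$path[1], after = 1)
  expect_equal(mtu_length(m, neutral_q(m), mtu2), L0, tolerance = 1e-15)
})

test_that("Fmax follows the volume / scaled fiber length formula", {
  # L_mt_s = L_mt_g collapses the scaling
  expect_equal(estimate_fmax(200, 10, 40, 40, 61), 200 / 10 * 61)
  # hand-computed: l_o_s = 10 * 44/40 = 11 cm, Fmax = 200/11 * 61
  expect_equal(estimate_fmax(200, 10, 40, 44, 61), 200 / 11 * 61,
               tolerance = 1e-12)
  expect_equal(200 / 11 * 61, 1109.0909, tolerance = 1e-4)
  # homogeneity: linear in Vol and sigma, inverse in l_o_g
  f <- estimate_fmax(200, 10, 40, 44, 61)
  expect_equal(estimate_fmax(200, 10, 40, 44, 122), 2 * f)
  expect_equal(estimate_fmax(400, 10, 40, 44, 61), 2 * f)
  expect_equal(estimate_fmax(200, 20, 40, 44, 61), f / 2)
  expect_error(estimate_fmax(-1, 10, 40, 44, 61), "mskuq_invalid_fmax_input")
  expect_error(estimate_fmax(200, 10, 40, 44, 0), "mskuq_invalid_fmax_input")
})

test_that("model JSON serialization round-trips losslessly", {
  m <- template_model_cached()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$mass, m$mass)
  expect_equal(m2$sigma, m$sigma)
  for (seg in names(m$segments)) {
    expect_equal(m2$segments[[seg]]$inertia, m$segments[[seg]]$inertia,
                 tolerance = 1e-12)
    expect_equal(m2$segments[[seg]]$landmarks_body,
                 m$segments[[seg]]$landmarks_body, tolerance = 1e-12)
  }
  for (nm in names(m$mtus)) {
    expect_equal(m2$mtus[[nm]]$Fmax, m$mtus[[nm]]$Fmax, tolerance = 1e-10)
  }
  # write -> read -> write is a fixed point
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("template model satisfies the structural contract", {
  m <- template_model_cached()
  expect_s3_class(m, "msk_model")
  expect_equal(sum(m$articulated), 10)
  expect_equal(length(m$segments), 7)
  expect_equal(length(m$mtus), 32)
  expect_equal(nrow(m$definition$landmarks), 37)  # 21 names, left mirrored
  # total segment mass equals the full mass budget
  expect_equal(sum(vapply(m$segments, `[[`, numeric(1), "mass")), 70.5,
               tolerance = 1e-9)
})
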