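# Joint reaction (contact) forces.

test_that("static standing ankle contact balances GRF minus foot weight", {
  m <- template_model_cached()
  tr <- generate_gait(m, template_params(motion_amplitude = 0))
  n <- length(tr$time)
  q <- tr$ground_truth$q; qd <- q * 0; qdd <- q * 0
  ext <- lapply(seq_len(n), function(t) mskuq:::grf_external(tr, t))
  jr <- joint_reaction(m, q, qd, qdd, muscle_forces = NULL, external = ext)
  foot_w <- m$segments$foot_r$mass * 9.80665
  # vertical balance of the foot free body: contact = foot weight - GRF
  expect_equal(jr$ankle_r$force[1, 2], foot_w - tr$grf$force[1, 2],
               tolerance = 1e-9)
  expect_equal(jr$ankle_r$magnitude[1],
               abs(tr$grf$force[1, 2]) - foot_w, tolerance = 1e-6)
})

test_that("zero muscle forces reduce contact to the intersegmental resultant", {
  m <- template_model_cached()
  tr <- template_gait_cached()
  res <- run_trial(m, tr)
  n <- length(tr$time)
  der <- differentiate(res$q, tr$time)
  ext <- lapply(seq_len(n), function(t) mskuq:::grf_external(tr, t))
  jr0 <- joint_reaction(m, res$q, der$xd, der$xdd, NULL, ext)
  jrz <- joint_reaction(m, res$q, der$xd, der$xdd,
                        res$muscle_forces * 0, ext)
  expect_equal(jr0$knee_r$force, jrz$knee_r$force, tolerance = 1e-12)
})

test_that("one-muscle pin-joint contact force matches the hand free-body solution", {
  # pendulum held static by a single 'muscle' from ground-fixed point:
  # use the double pendulum with a muscle crossing the second hinge
  dp <- toy_fixtures()$double_pendulum()
  l1 <- 0.5
  dp$mtus$m1 <- list(
    name = "m1", side = "r", Vol = 1, l_o_g = 1, L_mt_g = 1, Fmax = 500,
    path = list(
      list(body = "link1", role = "origin", pos_body = c(0.06, -l1 + 0.1, 0)),
      list(body = "link2", role = "insertion", pos_body = c(0.06, -0.1, 0))))
  q <- c(0, 0); qd <- c(0, 0); qdd <- c(0, 0)
  Fm <- matrix(120, 1, 1)
  jr <- joint_reaction(dp, matrix(q, 1), matrix(qd, 1), matrix(qdd, 1), Fm)
  # free body of link2 (static, gravity -y): 0 = F_contact - m2 g ŷ + F_m u
  # muscle pulls link2 towards link1: u = (p1 - p2)/|p1 - p2| = +y, so
  # F_contact = m2 g ŷ - F_m ŷ
  m2 <- dp$segments$link2$mass
  expected <- c(0, m2 * 9.80665, 0) - 120 * c(0, 1, 0)
  expect_equal(jr$hinge2$force[1, ], expected, tolerance = 1e-10)
})

test_that("joint reaction is antisymmetric between the two sides of a joint", {
  # the complementary (proximal) free body must give the exact negative:
  # equivalently distal + proximal sums to the total external balance,
  # which is zero for consistent data
  m <- template_model_cached()
  tr <- template_gait_cached()
  res <- run_trial(m, tr)
  der <- differentiate(res$q, tr$time)
  n <- length(tr$time)
  ext <- lapply(seq_len(n), function(t) mskuq:::grf_external(tr, t))
  g_vec <- c(0, -9.80665, 0)
  set.seed(88)
  for (t in sample(n, 4)) {
    fd <- mskuq:::fk_dynamics(m, res$q[t, ], der$xd[t, ], der$xdd[t, ])
    for (jn in c("knee_r", "hip_l")) {
      inside <- mskuq:::subtree_bodies(m, jn)
      outside <- setdiff(names(m$segments), inside)
      f_out <- c(0, 0, 0)
      for (b in outside) {
        seg <- m$segments[[b]]
        f_out <- f_out + seg$mass * (fd$dyn[[b]]$a_com - g_vec)
        if (!is.null(ext[[t]][[b]])) f_out <- f_out - ext[[t]][[b]]$force
      }
      for (mi in seq_along(m$mtus)) {
        u <- mskuq:::muscle_crossing(m, fd$st, m$mtus[[mi]], outside)
        if (!is.null(u)) f_out <- f_out - res$muscle_forces[t, mi] * u
      }
      jr <- joint_reaction(m, res$q[t, , drop = FALSE],
                           der$xd[t, , drop = FALSE],
                           der$xdd[t, , drop = FALSE],
                           res$muscle_forces[t, , drop = FALSE],
                           ext[t])
      expect_lt(max(abs(jr[[jn]]$force[1, ] + f_out)), 1e-6)
    }
  }
})
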