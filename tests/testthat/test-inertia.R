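# Two-density segment inertial properties.

test_that("single bone cylinder mass is density times volume", {
  # V = 100 cm^3 = 1e-4 m^3 at 1.42 g/cm^3 -> 0.142 kg
  L <- 0.1
  r <- sqrt(1e-4 / (pi * L))
  g <- list(parts = list(geometry_part("bone", "cylinder",
                                       list(radius = r, length = L))))
  ip <- compute_inertial_properties(g)
  expect_equal(ip$mass, 0.142, tolerance = 1e-12)
})

test_that("coincident equal-mass parts put the com at the shared centroid", {
  ctr <- c(0.01, -0.03, 0.02)
  g <- list(parts = list(
    geometry_part("soft_tissue", "cylinder", list(radius = 0.03, length = 0.2), ctr),
    geometry_part("soft_tissue", "ellipsoid", list(a = 0.03, b = 0.04, c = 0.05), ctr)))
  ip <- compute_inertial_properties(g)
  expect_equal(ip$com, ctr, tolerance = 1e-12)
})

test_that("composite inertia matches Monte-Carlo point-mass integration", {
  Rrot <- rot_axis_angle_test(c(1, 2, 3), 0.7)
  g <- list(parts = list(
    geometry_part("bone", "cylinder", list(radius = 0.02, length = 0.3),
                  c(0.05, 0, 0.01), Rrot),
    geometry_part("soft_tissue", "ellipsoid", list(a = 0.06, b = 0.12, c = 0.05),
                  c(0.02, -0.04, 0))))
  ip <- compute_inertial_properties(g)
  set.seed(7)
  n <- 3e5
  dens <- c(bone = 1420, soft_tissue = 1030)
  pts <- list(); ms <- c()
  # sample the cylinder directly in its local frame
  u <- matrix(stats::runif(3 * n), ncol = 3)
  rad <- 0.02 * sqrt(u[, 1]); th <- 2 * pi * u[, 2]
  loc <- cbind(rad * cos(th), 0.3 * (u[, 3] - 0.5), rad * sin(th))
  p_cyl <- t(Rrot %*% t(loc)) + matrix(c(0.05, 0, 0.01), n, 3, byrow = TRUE)
  m_cyl <- dens["bone"] * pi * 0.02^2 * 0.3 / n
  # sample the ellipsoid by rejection in scaled sphere coordinates
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * stats::runif(n)^(1 / 3)
  p_ell <- sweep(v, 2, c(0.06, 0.12, 0.05), `*`) +
    matrix(c(0.02, -0.04, 0), n, 3, byrow = TRUE)
  m_ell <- dens["soft_tissue"] * 4 / 3 * pi * 0.06 * 0.12 * 0.05 / n
  P <- rbind(p_cyl, p_ell)
  w <- c(rep(m_cyl, n), rep(m_ell, n))
  mass_mc <- sum(w)
  com_mc <- colSums(P * w) / mass_mc
  Pc <- sweep(P, 2, com_mc)
  I_mc <- matrix(0, 3, 3)
  r2 <- rowSums(Pc^2)
  I_mc[1, 1] <- sum(w * (r2 - Pc[, 1]^2))
  I_mc[2, 2] <- sum(w * (r2 - Pc[, 2]^2))
  I_mc[3, 3] <- sum(w * (r2 - Pc[, 3]^2))
  I_mc[1, 2] <- I_mc[2, 1] <- -sum(w * Pc[, 1] * Pc[, 2])
  I_mc[1, 3] <- I_mc[3, 1] <- -sum(w * Pc[, 1] * Pc[, 3])
  I_mc[2, 3] <- I_mc[3, 2] <- -sum(w * Pc[, 2] * Pc[, 3])
  expect_equal(ip$mass, mass_mc, tolerance = 1e-12)
  expect_lt(max(abs(ip$com - com_mc)), 2e-4)
  expect_lt(norm(ip$inertia - I_mc, "F") / norm(ip$inertia, "F"), 0.005)
})

test_that("segment inertia tensors are positive-definite with valid principal moments", {
  m <- template_model_cached()
  for (seg in m$segments) {
    ev <- eigen(seg$inertia, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lte(max(ev), sum(ev) - max(ev) + 1e-12)  # triangle inequality
  }
})

test_that("non-positive densities or dimensions raise named errors", {
  g <- list(parts = list(geometry_part("bone", "cylinder",
                                       list(radius = -0.01, length = 0.1))))
  expect_error(compute_inertial_properties(g), "mskuq_invalid_dimension")
  g2 <- list(parts = list(geometry_part("bone", "cylinder",
                                        list(radius = 0.01, length = 0.1))),
             densities = c(bone = -1, soft_tissue = 1.03))
  expect_error(compute_inertial_properties(g2), "mskuq_invalid_density")
})
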