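# Static optimization of muscle redundancy: per-frame box-constrained
# quadratic program minimizing the sum of squared activations plus a
# quadratic penalty on reserve actuator torques.
#
# With reserve torques eliminated (Mres = M - G a), the problem reduces to
#   min_a  a'a + w ||(M - G a)/Msc||^2 ,  0 <= a <= 1
# a strictly convex box QP solved exactly by a primal active-set method.

# Solve min a' A a - 2 b' a, 0 <= a <= 1, A symmetric positive-definite.
solve_box_qp <- function(A, b, a0 = NULL, max_cycles = 200) {
  n <- length(b)
  a <- if (is.null(a0)) rep(0.5, n) else pmin(pmax(a0, 0), 1)
  lower <- rep(FALSE, n); upper <- rep(FALSE, n)
  for (cycle in seq_len(max_cycles)) {
    free <- !(lower | upper)
    repeat {
      if (any(free)) {
        af <- rep(0, n); af[upper] <- 1
        rhs <- b[free] - if (any(!free)) A[free, !free, drop = FALSE] %*% af[!free] else 0
        sol <- solve(A[free, free, drop = FALSE], rhs)
        a[free] <- as.vector(sol)
      }
      a[lower] <- 0; a[upper] <- 1
      viol_lo <- free & (a < -1e-14)
      viol_hi <- free & (a > 1 + 1e-14)
      if (!any(viol_lo | viol_hi)) break
      # clamp the worst violator and re-solve
      if (any(viol_lo)) {
        i <- which(viol_lo)[which.min(a[viol_lo])]
        lower[i] <- TRUE
      } else {
        i <- which(viol_hi)[which.max(a[viol_hi])]
        upper[i] <- TRUE
      }
      free <- !(lower | upper)
    }
    # KKT: gradient of the objective is 2(Aa - b)
    g <- 2 * (A %*% a - b)
    rel_lo <- lower & (g < -1e-10)
    rel_hi <- upper & (g > 1e-10)
    if (!any(rel_lo | rel_hi)) {
      kkt <- max(c(0, abs(g[!(lower | upper)]),
                   -pmin(g[lower], 0), pmax(g[upper], 0)))
      return(list(a = as.vector(a), kkt = kkt, converged = TRUE))
    }
    i <- which.max(abs(g) * (rel_lo | rel_hi))
    lower[i] <- FALSE; upper[i] <- FALSE
  }
  list(a = as.vector(a), kkt = Inf, converged = FALSE)
}

#' Static optimization of muscle forces
#'
#' Per frame, solves for activations `a` in `[0, 1]` minimizing
#' `sum(a^2) + w_res * sum((Mres / M_scale)^2)` subject to moment
#' equilibrium `r' (a * Fmax) + Mres = M` at every articulated degree of
#' freedom. Reserve torques take up whatever the muscles cannot produce and
#' are heavily penalized; large reserves downstream mark a simulation as
#' unsuccessful. Force-length-velocity muscle properties are deliberately
#' not modelled.
#'
#' @param moment_arm_matrix single matrix (MTUs x DOFs) or list of per-frame
#'   matrices, meters
#' @param Fmax_vector maximum isometric forces, N
#' @param net_moments matrix (frames x DOFs), N m
#' @param reserve_config list with `w_res` (penalty weight, default 1e3) and
#'   `M_scale` (torque scale, N m, default 1)
#' @return list with `activations`, `forces` (frames x MTUs),
#'   `reserves` (frames x DOFs), `kkt`, `objective`, `failed` (logical per
#'   frame)
#' @export
static_optimization <- function(moment_arm_matrix, Fmax_vector, net_moments,
                                reserve_config = list()) {
  w_res <- reserve_config$w_res %||% 1e3
  M_scale <- reserve_config$M_scale %||% 1
  if (any(Fmax_vector <= 0)) stop("mskuq_invalid_fmax_input: Fmax must be > 0", call. = FALSE)
  if (is.vector(net_moments)) net_moments <- matrix(net_moments, nrow = 1)
  n <- nrow(net_moments)
  per_frame <- is.list(moment_arm_matrix) && !is.matrix(moment_arm_matrix)
  nm <- length(Fmax_vector)
  act <- matrix(0, n, nm); res <- matrix(0, n, ncol(net_moments))
  kkt <- numeric(n); obj <- numeric(n); failed <- logical(n)
  a_prev <- NULL
  for (t in seq_len(n)) {
    r <- if (per_frame) moment_arm_matrix[[t]] else moment_arm_matrix
    G <- t(r * Fmax_vector)          # DOFs x MTUs
    M <- net_moments[t, ]
    if (any(!is.finite(G)) || any(!is.finite(M))) {
      failed[t] <- TRUE; kkt[t] <- Inf
      next
    }
    s <- w_res / M_scale^2
    A <- diag(nm) + s * crossprod(G)
    b <- s * as.vector(crossprod(G, M))
    sol <- solve_box_qp(A, b, a0 = a_prev)
    a_prev <- sol$a
    act[t, ] <- sol$a
    res[t, ] <- M - as.vector(G %*% sol$a)
    kkt[t] <- sol$kkt
    obj[t] <- sum(sol$a^2) + w_res * sum((res[t, ] / M_scale)^2)
    failed[t] <- !sol$converged
  }
  colnames(act) <- rownames(if (per_frame) moment_arm_matrix[[1]] else moment_arm_matrix)
  colnames(res) <- colnames(net_moments)
  list(activations = act,
       forces = sweep(act, 2, Fmax_vector, `*`),
       reserves = res, kkt = kkt, objective = obj, failed = failed)
}
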