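# Inverse dynamics: velocity/acceleration propagation over the tree and
# generalized forces by the Jacobian-transpose (d'Alembert) formulation.

# Per-body angular velocity/acceleration and origin acceleration at one frame.
fk_dynamics <- function(model, q, qd, qdd) {
  st <- fk_state(model, q)
  nb <- names(st$poses)
  dyn <- stats::setNames(vector("list", length(nb)), nb)
  ci <- 0L
  for (j in model$joints) {
    if (j$parent == "ground") {
      om_p <- c(0, 0, 0); al_p <- c(0, 0, 0)
      Rp <- diag(3); pp <- c(0, 0, 0); a_pp <- c(0, 0, 0)
    } else {
      dp <- dyn[[j$parent]]
      om_p <- dp$omega; al_p <- dp$alpha
      Rp <- st$poses[[j$parent]]$R; pp <- st$poses[[j$parent]]$p
      a_pp <- dp$a_origin
    }
    tj <- c(0, 0, 0); a_trans <- c(0, 0, 0)
    om <- om_p; al <- al_p
    idx0 <- ci
    for (d in j$dofs) {
      ci <- ci + 1L
      if (d$type == "trans") {
        if (j$parent != "ground") {
          stop("mskuq_unsupported: translational dof below a rotating parent",
               call. = FALSE)
        }
        tj <- tj + d$axis * q[ci]
        a_trans <- a_trans + d$axis * qdd[ci]
      } else {
        s <- st$axis_w[, ci]
        al <- al + s * qdd[ci] + cross3(om, s * qd[ci])
        om <- om + s * qd[ci]
      }
    }
    w <- pp + as.vector(Rp %*% (j$loc_parent + tj))
    # acceleration of the joint point (fixed in parent, plus root translation)
    rw <- w - pp
    a_w <- a_pp + cross3(al_p, rw) + cross3(om_p, cross3(om_p, rw)) + a_trans
    pc <- st$poses[[j$child]]$p
    rc <- pc - w
    a_origin <- a_w + cross3(al, rc) + cross3(om, cross3(om, rc))
    dyn[[j$child]] <- list(omega = om, alpha = al, a_origin = a_origin)
  }
  for (b in nb) {
    seg <- model$segments[[b]]
    pose <- st$poses[[b]]
    com_w <- pose_apply(pose, seg$com)
    d <- dyn[[b]]
    r <- com_w - pose$p
    dyn[[b]]$com_w <- com_w
    dyn[[b]]$a_com <- d$a_origin + cross3(d$alpha, r) +
      cross3(d$omega, cross3(d$omega, r))
  }
  list(st = st, dyn = dyn)
}

# Generalized forces at one frame. ext is a named list (by body) of
# list(force, point, torque) in world coordinates (torque optional).
id_frame <- function(model, q, qd, qdd, ext = list(), gravity = GRAVITY) {
  fd <- fk_dynamics(model, q, qd, qdd)
  g_vec <- c(0, -gravity, 0)
  nq <- length(model$coord_names)
  tau <- numeric(nq)
  # per-body net inertial-minus-applied wrench about its com
  fb <- list(); nb_ <- list()
  for (b in names(model$segments)) {
    seg <- model$segments[[b]]
    d <- fd$dyn[[b]]
    R <- fd$st$poses[[b]]$R
    Iw <- R %*% seg$inertia %*% t(R)
    f <- seg$mass * (d$a_com - g_vec)
    n <- as.vector(Iw %*% d$alpha) + cross3(d$omega, as.vector(Iw %*% d$omega))
    e <- ext[[b]]
    if (!is.null(e)) {
      f <- f - e$force
      n <- n - cross3(e$point - d$com_w, e$force)
      if (!is.null(e$torque)) n <- n - e$torque
    }
    fb[[b]] <- f; nb_[[b]] <- n
  }
  for (b in names(model$segments)) {
    for (k in chain_coords(model, b)) {
      if (fd$st$type_tr[k]) {
        tau[k] <- tau[k] + sum(fd$st$axis_w[, k] * fb[[b]])
      } else {
        mom <- cross3(fd$dyn[[b]]$com_w - fd$st$point_w[, k], fb[[b]]) + nb_[[b]]
        tau[k] <- tau[k] + sum(fd$st$axis_w[, k] * mom)
      }
    }
  }
  stats::setNames(tau, model$coord_names)
}

#' Numerical differentiation on a uniform time grid
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param x numeric matrix (frames x variables) or vector
#' @param time strictly increasing uniform time grid (s)
#' @return list with `xd` and `xdd`, same shape as `x`
#' @export
differentiate <- function(x, time) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 3) stop("mskuq_too_few_frames: need >= 3 frames", call. = FALSE)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("mskuq_nonuniform_grid: time grid must be uniform", call. = FALSE)
  }
  h <- dt[1]
  xd <- x; xdd <- x
  xd[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * h)
  xd[1, ] <- (x[2, ] - x[1, ]) / h
  xd[n, ] <- (x[n, ] - x[n - 1, ]) / h
  xdd[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - 2 * x[2:(n - 1), , drop = FALSE] +
                         x[1:(n - 2), , drop = FALSE]) / h^2
  xdd[1, ] <- xdd[2, ]
  xdd[n, ] <- xdd[n - 1, ]
  list(xd = xd, xdd = xdd)
}

#' Inverse dynamics over a motion
#'
#' Net generalized forces at every coordinate by recursive Newton-Euler
#' (Jacobian-transpose formulation) given joint kinematics and external
#' ground reaction loads. The root (pelvis) residual wrench is returned
#' explicitly rather than discarded: for dynamically consistent data it is
#' zero.
#'
#' @param model an `msk_model`
#' @param q,qd,qdd matrices (frames x coordinates)
#' @param external per-frame external loads: list of named lists
#'   (by body) with `force` (N), `point` (world, m), optional `torque`
#'   (N m); or NULL for none.
#' @return list with `moments` (frames x articulated coordinates) and
#'   `residual` (frames x 6 root coordinates)
#' @export
inverse_dynamics <- function(model, q, qd, qdd, external = NULL) {
  n <- nrow(q)
  art <- which(model$articulated)
  moments <- matrix(0, n, length(art),
                    dimnames = list(NULL, model$coord_names[art]))
  residual <- matrix(0, n, 6,
                     dimnames = list(NULL, model$coord_names[!model$articulated]))
  for (t in seq_len(n)) {
    ext <- if (is.null(external)) list() else external[[t]]
    tau <- id_frame(model, q[t, ], qd[t, ], qdd[t, ], ext)
    moments[t, ] <- tau[art]
    residual[t, ] <- tau[!model$articulated]
  }
  list(moments = moments, residual = residual)
}

# external-load list for a GRF applied at the CoP on one foot
grf_external <- function(trial, t) {
  f <- trial$grf$force[t, ]
  if (all(abs(f) < 1e-12)) return(list())
  e <- list(list(force = f, point = trial$grf$cop[t, ],
                 torque = trial$grf$torque[t, ]))
  names(e) <- trial$grf$foot
  e
}
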