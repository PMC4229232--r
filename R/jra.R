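# Joint reaction analysis: bone-on-bone contact force at each joint from a
# free-body analysis of the distal subtree, subtracting the pull of every
# muscle crossing the joint along its line of action.

# bodies in the subtree rooted at the child of a joint
subtree_bodies <- function(model, joint_name) {
  child <- model$joints[[joint_name]]$child
  names(model$chains)[vapply(model$chains, function(ch) joint_name %in% ch,
                             logical(1))]
}

# for a muscle crossing the joint boundary, the unit line of action pulling
# the distal subtree towards the proximal side, and whether it crosses
muscle_crossing <- function(model, st, mtu, inside) {
  path <- mtu$path
  np <- length(path)
  pw <- matrix(0, 3, np)
  for (p in seq_len(np)) {
    pw[, p] <- pose_apply(st$poses[[path[[p]]$body]], path[[p]]$pos_body)
  }
  memb <- vapply(path, function(pp) pp$body %in% inside, logical(1))
  if (all(memb) || all(!memb)) return(NULL)
  for (p in seq_len(np - 1L)) {
    if (memb[p] != memb[p + 1L]) {
      i_in <- if (memb[p]) p else p + 1L
      i_out <- if (memb[p]) p + 1L else p
      d <- pw[, i_out] - pw[, i_in]
      return(d / vnorm(d))
    }
  }
  NULL
}

#' Joint reaction (contact) forces
#'
#' For each articulated joint, the contact force transmitted to the distal
#' segment: the net inertial-minus-gravitational force of the distal
#' subtree, minus external loads applied to it and minus the pull of every
#' musculotendon unit crossing the joint, applied along the path segment
#' spanning the joint. The force on the proximal side is the exact negative
#' (action-reaction).
#'
#' @param model an `msk_model`
#' @param q,qd,qdd matrices (frames x coordinates)
#' @param muscle_forces matrix (frames x MTUs), N; NULL for none
#' @param external per-frame external loads as in [inverse_dynamics()]
#' @param gravity gravitational acceleration, m/s^2
#' @return named list per joint: list with `force` (frames x 3, N, on the
#'   distal segment) and `magnitude` (frames, N)
#' @export
joint_reaction <- function(model, q, qd, qdd, muscle_forces = NULL,
                           external = NULL, gravity = GRAVITY) {
  n <- nrow(q)
  g_vec <- c(0, -gravity, 0)
  joint_names <- setdiff(names(model$joints), "ground_pelvis")
  out <- stats::setNames(vector("list", length(joint_names)), joint_names)
  for (jn in joint_names) {
    out[[jn]] <- list(force = matrix(0, n, 3), magnitude = numeric(n))
  }
  mtu_names <- names(model$mtus)
  for (t in seq_len(n)) {
    fd <- fk_dynamics(model, q[t, ], qd[t, ], qdd[t, ])
    ext <- if (is.null(external)) list() else external[[t]]
    for (jn in joint_names) {
      inside <- subtree_bodies(model, jn)
      f <- c(0, 0, 0)
      for (b in inside) {
        seg <- model$segments[[b]]
        f <- f + seg$mass * (fd$dyn[[b]]$a_com - g_vec)
        if (!is.null(ext[[b]])) f <- f - ext[[b]]$force
      }
      if (!is.null(muscle_forces)) {
        for (mi in seq_along(mtu_names)) {
          Fm <- muscle_forces[t, mi]
          if (Fm == 0) next
          u <- muscle_crossing(model, fd$st, model$mtus[[mtu_names[mi]]], inside)
          if (!is.null(u)) f <- f - Fm * u
        }
      }
      out[[jn]]$force[t, ] <- f
      out[[jn]]$magnitude[t] <- vnorm(f)
    }
  }
  out
}
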