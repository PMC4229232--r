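# Inverse kinematics: per-frame weighted least-squares marker tracking,
# damped Gauss-Newton with analytic Jacobians, warm-started across frames.

#' Inverse kinematics from marker trajectories
#'
#' Per frame, finds the coordinate vector minimizing the weighted sum of
#' squared distances between model landmark positions and observed markers.
#' Solved by damped Gauss-Newton with analytic geometric Jacobians and warm
#' starts from the previous frame for continuity.
#'
#' @param model an `msk_model`
#' @param trial a `gait_trial` (see [generate_gait()]) or any list with
#'   `markers` (`list(names, xyz)` with `xyz` an array frames x markers x 3)
#' @param weights optional named marker weights (default 1)
#' @param q0 initial guess for the first frame (default neutral pose)
#' @param tol convergence tolerance on the coordinate step (rad / m)
#' @param max_iter maximum Gauss-Newton iterations per frame
#' @return list with `q` (frames x coordinates), `rms` (per-frame RMS marker
#'   error, m) and `flagged` (frames that did not converge)
#' @export
inverse_kinematics <- function(model, trial, weights = NULL, q0 = NULL,
                               tol = 1e-10, max_iter = 60) {
  mk <- trial$markers
  names_mk <- mk$names
  use <- names_mk %in% all_landmark_names(model)
  if (!any(use)) stop("mskuq_insufficient_markers: no markers match model landmarks", call. = FALSE)
  names_mk <- names_mk[use]
  lm_body <- landmark_body_table(model)
  seg_of <- lm_body$segment[match(names_mk, lm_body$name)]
  check_marker_coverage(model, names_mk, seg_of)
  w <- rep(1, length(names_mk))
  if (!is.null(weights)) {
    hit <- names_mk %in% names(weights)
    w[hit] <- weights[names_mk[hit]]
  }
  sw <- sqrt(w)
  n <- dim(mk$xyz)[1]
  nq <- length(model$coord_names)
  Q <- matrix(0, n, nq, dimnames = list(NULL, model$coord_names))
  rms <- numeric(n)
  flagged <- integer(0)
  q <- if (is.null(q0)) neutral_q(model) else q0
  pb_list <- lapply(seq_along(names_mk), function(i) {
    model$segments[[seg_of[i]]]$landmarks_body[names_mk[i], ]
  })
  obs_all <- mk$xyz[, use, , drop = FALSE]
  for (t in seq_len(n)) {
    obs <- matrix(obs_all[t, , ], ncol = 3)
    ok_mk <- rowSums(is.na(obs)) == 0
    converged <- FALSE
    lambda <- 1e-6
    for (it in seq_len(max_iter)) {
      st <- fk_state(model, q)
      res <- numeric(0); J <- NULL
      rows <- which(ok_mk)
      Jm <- matrix(0, 3 * length(rows), nq)
      rv <- numeric(3 * length(rows))
      for (ii in seq_along(rows)) {
        i <- rows[ii]
        pw <- pose_apply(st$poses[[seg_of[i]]], pb_list[[i]])
        Ji <- point_jacobian(model, st, seg_of[i], pw)
        idx <- (3 * ii - 2):(3 * ii)
        Jm[idx, ] <- sw[i] * Ji
        rv[idx] <- sw[i] * (pw - obs[i, ])
      }
      g <- crossprod(Jm, rv)
      H <- crossprod(Jm)
      step <- tryCatch(
        -solve(H + lambda * diag(nq), g),
        error = function(e) -solve(H + 1e-3 * diag(nq), g))
      q <- q + as.vector(step)
      if (max(abs(step)) < tol) { converged <- TRUE; break }
    }
    st <- fk_state(model, q)
    err2 <- 0; nokk <- 0
    for (i in which(ok_mk)) {
      pw <- pose_apply(st$poses[[seg_of[i]]], pb_list[[i]])
      err2 <- err2 + sum((pw - obs[i, ])^2); nokk <- nokk + 1
    }
    rms[t] <- sqrt(err2 / max(nokk, 1))
    if (!converged) {
      flagged <- c(flagged, t)
      warning("mskuq_ik_nonconvergence: frame ", t, " did not converge",
              call. = FALSE)
    }
    Q[t, ] <- q
  }
  list(q = Q, rms = rms, flagged = flagged)
}

all_landmark_names <- function(model) {
  unlist(lapply(model$segments, function(s) rownames(s$landmarks_body)),
         use.names = FALSE)
}

landmark_body_table <- function(model) {
  dplyr::bind_rows(lapply(model$segments, function(s) {
    tibble::tibble(segment = s$name, name = rownames(s$landmarks_body))
  }))
}

check_marker_coverage <- function(model, names_mk, seg_of) {
  branches <- list(pelvis = "pelvis",
                   leg_r = c("thigh_r", "shank_r", "foot_r"),
                   leg_l = c("thigh_l", "shank_l", "foot_l"))
  for (bn in names(branches)) {
    if (sum(seg_of %in% branches[[bn]]) < 3) {
      stop("mskuq_insufficient_markers: branch '", bn,
           "' has fewer than 3 markers", call. = FALSE)
    }
  }
  invisible(TRUE)
}
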