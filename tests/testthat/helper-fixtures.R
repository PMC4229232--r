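# Shared fixtures, built once per test run.

template_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- generate_template_model()
    m
  }
})

template_gait_cached <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) tr <<- generate_gait(template_model_cached())
    tr
  }
})

template_vars_cached <- local({
  v <- NULL
  function() {
    if (is.null(v)) {
      v <<- suppressMessages(define_stochastic_variables(template_model_cached()))
    }
    v
  }
})

# random valid landmark cloud for one leg + pelvis (jittered template)
random_landmark_cloud <- function() {
  m <- template_model_cached()
  lm <- m$definition$landmarks
  lm$x <- lm$x + stats::rnorm(nrow(lm), 0, 0.01)
  lm$y <- lm$y + stats::rnorm(nrow(lm), 0, 0.01)
  lm$z <- lm$z + stats::rnorm(nrow(lm), 0, 0.01)
  lm
}

# independently coded Gram-Schmidt frame oracle, mirroring the documented
# per-segment recipes but through plain sequential orthogonalization
gs_frame_oracle <- function(primary, primary_label, hint, hint_label) {
  e1 <- primary / sqrt(sum(primary^2))
  h2 <- hint - sum(hint * e1) * e1
  e2 <- h2 / sqrt(sum(h2^2))
  labs <- c(primary_label, hint_label)
  third <- setdiff(c("x", "y", "z"), labs)
  ref <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  sgn <- sum(pracma::cross(ref[[primary_label]], ref[[hint_label]]) * ref[[third]])
  e3 <- sgn * pracma::cross(e1, e2)
  out <- list()
  out[[primary_label]] <- e1; out[[hint_label]] <- e2; out[[third]] <- e3
  cbind(out$x, out$y, out$z)
}

# Rodrigues rotation for building test fixtures
rot_axis_angle_test <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal fake ensemble for statistics tests
make_fake_ensemble <- function(trace, samples, success = rep(TRUE, nrow(trace)),
                               output_names = colnames(trace)) {
  # trace rows correspond to successful trials only
  structure(list(
    outputs = NULL,
    samples = list(values = samples, variables = NULL, seed = 0, method = "LHS"),
    success = success, reasons = ifelse(success, "ok", "fake"),
    trace = trace, convergence = NULL, config = run_config(),
    output_names = output_names, body_weight = 700), class = "msk_ensemble")
}

contact_output_names <- function(npts = 101) {
  as.vector(vapply(c("contact_hip_r", "contact_knee_r", "contact_ankle_r"),
                   function(o) paste0("contact:", o, ":", seq_len(npts)),
                   character(npts)))
}
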