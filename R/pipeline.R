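# Monte-Carlo pipeline: per-trial simulation (IK -> derivatives -> ID ->
# static optimization -> joint reaction), success classification by the
# reserve-actuator rule, stance normalization and convergence monitoring.

#' Default run configuration
#'
#' Single source of the study's scalar constants: the reserve-based failure
#' threshold (5% of the peak joint moment), the convergence rule (last 10%
#' of simulations within 2% of the final mean and SD), the significance
#' threshold p < 0.001 and the R-squared reporting thresholds 0.2/0.7, the
#' musculotendon point SD (5 mm), the maximum-tension range (35-137 N/cm^2)
#' and the 101-point stance grid.
#'
#' @param ... overrides of any default
#' @export
run_config <- function(...) {
  cfg <- list(
    n_samples = 500, seed = 42,
    point_sd_mm = 5, sigma_lo = 35, sigma_hi = 137,
    lw_ratio_threshold = 3,
    reserve_fraction = 0.05,
    convergence_window = 0.10, convergence_tol = 0.02,
    convergence_abs_floor = 1e-6,
    p_threshold = 0.001, r2_lo = 0.2, r2_hi = 0.7,
    stance_points = 101L,
    w_res = 1e3, M_scale = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("mskuq_unknown_config: ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

#' Run the full per-trial simulation stack
#'
#' Inverse kinematics, numerical differentiation, inverse dynamics, static
#' optimization and joint reaction analysis, in order. Stage failures are
#' captured in the result, not raised.
#'
#' @param model an `msk_model`
#' @param trial a `gait_trial`
#' @param config list from [run_config()]
#' @return a `trial_result`: `q`, `ik_rms`, `moments`, `residual`,
#'   `activations`, `muscle_forces`, `reserves`, `contact`, `success`
#'   (before reserve classification: did all stages run), `stage` (failure
#'   tag or "ok"), `time`, `stance_window`, `body_weight`
#' @export
run_trial <- function(model, trial, config = run_config()) {
  res <- list(time = trial$time, stance_window = trial$stance_window,
              body_weight = trial$body_weight, success = FALSE, stage = "ok")
  class(res) <- "trial_result"
  out <- tryCatch({
    ik <- inverse_kinematics(model, trial)
    res$q <- ik$q; res$ik_rms <- ik$rms
    der <- differentiate(ik$q, trial$time)
    n <- nrow(ik$q)
    external <- lapply(seq_len(n), function(t) grf_external(trial, t))
    idr <- inverse_dynamics(model, ik$q, der$xd, der$xdd, external)
    res$moments <- idr$moments; res$residual <- idr$residual
    arms <- lapply(seq_len(n), function(t) moment_arms(model, ik$q[t, ]))
    Fmax <- vapply(model$mtus, `[[`, numeric(1), "Fmax")
    so <- static_optimization(arms, Fmax, idr$moments,
                              list(w_res = config$w_res, M_scale = config$M_scale))
    res$activations <- so$activations
    res$muscle_forces <- so$forces
    res$reserves <- so$reserves
    res$so_failed_frames <- which(so$failed)
    jr <- joint_reaction(model, ik$q, der$xd, der$xdd, so$forces, external)
    res$contact <- jr
    res$success <- TRUE
    res
  }, error = function(e) {
    res$stage <- conditionMessage(e)
    res
  })
  out
}

#' Classify a trial as successful or not by the reserve-actuator rule
#'
#' A simulation is unsuccessful if, at any articulated degree of freedom
#' and any stance frame, the reserve torque magnitude exceeds the given
#' fraction (default 5%) of that DOF's peak net moment magnitude over
#' stance — i.e. joint dynamic equilibrium required non-negligible
#' non-muscular torque.
#'
#' @param result a `trial_result`
#' @param peak_moment_fraction threshold fraction (default 0.05)
#' @return list with `success` (logical) and `reason` (character)
#' @export
classify_success <- function(result, peak_moment_fraction = 0.05) {
  if (!isTRUE(result$success)) {
    return(list(success = FALSE, reason = paste0("stage_failure: ", result$stage)))
  }
  if (length(result$so_failed_frames) > 0) {
    return(list(success = FALSE, reason = "static_optimization_failed_frames"))
  }
  sw <- result$stance_window
  idx <- sw[1]:sw[2]
  M <- abs(result$moments[idx, , drop = FALSE])
  Rv <- abs(result$reserves[idx, , drop = FALSE])
  peaks <- apply(M, 2, max)
  for (j in seq_len(ncol(M))) {
    if (any(Rv[, j] > peak_moment_fraction * peaks[j])) {
      return(list(success = FALSE,
                  reason = paste0("reserve_exceeded: ", colnames(M)[j])))
    }
  }
  list(success = TRUE, reason = "ok")
}

#' Resample trial outputs to the stance grid and normalize forces
#'
#' Linear time-resampling of every output to a 0-100% stance grid; joint
#' angles in degrees, moments in N m, muscle and joint contact forces in
#' multiples of body weight.
#'
#' @param result a `trial_result`
#' @param body_weight body weight, N (default from the result)
#' @param stance_window frame window (default from the result)
#' @param n_points grid resolution (default 101)
#' @return list of matrices on the stance grid: `pct`, `angles_deg`,
#'   `moments`, `muscle_forces_bw`, `contact_bw`
#' @export
normalize_outputs <- function(result, body_weight = result$body_weight,
                              stance_window = result$stance_window,
                              n_points = 101L) {
  idx <- stance_window[1]:stance_window[2]
  if (length(idx) < 2) stop("mskuq_empty_stance: stance window too short", call. = FALSE)
  t0 <- result$time[idx]
  pct_src <- (t0 - t0[1]) / (t0[length(t0)] - t0[1]) * 100
  pct <- seq(0, 100, length.out = n_points)
  rs <- function(M) {
    apply(M[idx, , drop = FALSE], 2, function(col) {
      stats::approx(pct_src, col, xout = pct)$y
    })
  }
  art <- grep("^pelvis_", colnames(result$q), invert = TRUE)
  contact <- do.call(cbind, lapply(names(result$contact), function(jn) {
    result$contact[[jn]]$magnitude
  }))
  colnames(contact) <- paste0("contact_", names(result$contact))
  list(pct = pct,
       angles_deg = rs(result$q[, art, drop = FALSE] * 180 / pi),
       moments = rs(result$moments),
       muscle_forces_bw = rs(result$muscle_forces / body_weight),
       contact_bw = rs(contact / body_weight))
}

#' Convergence of running ensemble statistics
#'
#' For each output variable (frame-resolved), checks that the running means
#' and standard deviations over the last fraction of the simulations stay
#' within the tolerance of the final mean and SD. Variables whose final
#' value is below an absolute floor are checked with the floor as absolute
#' tolerance instead (relative tolerance is meaningless at zero).
#'
#' @param trace matrix (trials x output values)
#' @param window_fraction last fraction of simulations to inspect (0.10)
#' @param tolerance relative tolerance (0.02)
#' @param abs_floor absolute floor in native units (1e-6)
#' @return list with `converged` (overall), `mean_ok`, `sd_ok` (per output
#'   value) and `n`
#' @export
check_convergence <- function(trace, window_fraction = 0.10, tolerance = 0.02,
                              abs_floor = 1e-6) {
  n <- nrow(trace)
  if (n < 10) stop("mskuq_too_few_trials: need >= 10 successful trials", call. = FALSE)
  k <- seq_len(n)
  cmean <- apply(trace, 2, cumsum) / k
  csq <- apply(trace^2, 2, cumsum)
  # running unbiased SD
  cvar <- (csq - k * cmean^2) / pmax(k - 1, 1)
  csd <- sqrt(pmax(cvar, 0))
  w0 <- max(2L, ceiling((1 - window_fraction) * n))
  win <- w0:n
  ok_stat <- function(run, final) {
    tol <- ifelse(abs(final) < abs_floor, abs_floor, tolerance * abs(final))
    dev <- abs(sweep(run[win, , drop = FALSE], 2, final))
    apply(sweep(dev, 2, tol, `<=`), 2, all)
  }
  mean_ok <- ok_stat(cmean, cmean[n, ])
  sd_ok <- ok_stat(csd, csd[n, ])
  list(converged = all(mean_ok & sd_ok), mean_ok = mean_ok, sd_ok = sd_ok,
       n = n)
}

#' Run the Monte-Carlo probabilistic gait study
#'
#' Draws a Latin-hypercube sample of the stochastic input variables, builds
#' one perturbed model per row, runs the full simulation stack on the gait
#' trial with each, classifies success by the reserve rule, excludes
#' unsuccessful trials from analysis, and computes the running-statistics
#' convergence trace on the successful trials.
#'
#' @param baseline baseline `msk_model`
#' @param gait a `gait_trial`
#' @param variables tibble from [define_stochastic_variables()]
#' @param N number of simulations
#' @param seed integer seed for the sample
#' @param config list from [run_config()]
#' @param progress print per-trial status lines
#' @return an `msk_ensemble`: `outputs` (list of per-trial normalized
#'   outputs), `samples`, `success`, `reasons`, `trace`, `convergence`,
#'   `config`, `output_names`
#' @export
run_monte_carlo <- function(baseline, gait, variables, N = 500, seed = 42,
                            config = run_config(), progress = FALSE) {
  stopifnot(N >= 10)
  samples <- lhs_sample(variables, N, seed)
  outputs <- vector("list", N)
  success <- logical(N)
  reasons <- character(N)
  for (i in seq_len(N)) {
    tr <- tryCatch({
      m_i <- instantiate_model(baseline, variables, samples$values[i, ])
      run_trial(m_i, gait, config)
    }, error = function(e) {
      r <- list(success = FALSE, stage = conditionMessage(e))
      class(r) <- "trial_result"
      r
    })
    cls <- classify_success(tr, config$reserve_fraction)
    success[i] <- cls$success
    reasons[i] <- cls$reason
    if (cls$success) {
      outputs[[i]] <- normalize_outputs(tr, n_points = config$stance_points)
    }
    if (progress) {
      message(sprintf("trial %d/%d: %s", i, N,
                      if (cls$success) "ok" else cls$reason))
    }
  }
  if (mean(success) < 0.5) {
    stop("mskuq_excess_failures: more than 50% of trials unsuccessful",
         call. = FALSE)
  }
  ok <- which(success)
  trace <- t(vapply(ok, function(i) flatten_outputs(outputs[[i]])$values,
                    flatten_outputs(outputs[[ok[1]]])$values))
  out_names <- flatten_outputs(outputs[[ok[1]]])$names
  colnames(trace) <- out_names
  conv <- if (length(ok) >= 10) {
    check_convergence(trace, config$convergence_window, config$convergence_tol,
                      config$convergence_abs_floor)
  } else NULL
  structure(list(outputs = outputs, samples = samples, success = success,
                 reasons = reasons, trace = trace, convergence = conv,
                 config = config, output_names = out_names,
                 body_weight = gait$body_weight),
            class = "msk_ensemble")
}

# flatten one trial's normalized outputs into a named vector
flatten_outputs <- function(no) {
  mats <- list(angle = no$angles_deg, moment = no$moments,
               muscle = no$muscle_forces_bw, contact = no$contact_bw)
  vals <- numeric(0); nms <- character(0)
  for (g in names(mats)) {
    M <- mats[[g]]
    for (j in seq_len(ncol(M))) {
      vals <- c(vals, M[, j])
      nms <- c(nms, paste0(g, ":", colnames(M)[j], ":", seq_len(nrow(M))))
    }
  }
  list(values = vals, names = nms)
}

#' @export
print.msk_ensemble <- function(x, ...) {
  cat("<msk_ensemble> ", length(x$success), " trials, ",
      sum(x$success), " successful (",
      round(100 * mean(!x$success), 1), "% unsuccessful)",
      if (!is.null(x$convergence)) {
        paste0("; converged: ", x$convergence$converged)
      } else "", "\n", sep = "")
  invisible(x)
}
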