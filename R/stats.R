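# Ensemble statistics: per-stance-percent mean/SD/range bands, summary
# tables, and the input-output correlation analysis with significance
# thresholds.

#' Per-stance-percent ensemble bands
#'
#' Mean, unbiased SD, min, max and range of every output at every stance
#' percent across the successful trials, plus per-output aggregates
#' (mean-over-stance and maximum SD and range).
#'
#' @param ensemble an `msk_ensemble`
#' @return an `msk_bands`: list with `bands` (tibble: `group`, `output`,
#'   `pct`, `mean`, `sd`, `min`, `max`, `range`) and `summary` (tibble:
#'   `group`, `output`, `mean_sd`, `max_sd`, `mean_range`, `max_range`)
#' @export
ensemble_bands <- function(ensemble) {
  ok <- which(ensemble$success)
  if (length(ok) < 2) stop("mskuq_too_few_trials: need >= 2 successful trials", call. = FALSE)
  trace <- ensemble$trace
  parts <- strsplit(ensemble$output_names, ":", fixed = TRUE)
  group <- vapply(parts, `[[`, "", 1)
  output <- vapply(parts, `[[`, "", 2)
  frame <- as.integer(vapply(parts, `[[`, "", 3))
  npts <- max(frame)
  pct <- (frame - 1) / (npts - 1) * 100
  mu <- unname(colMeans(trace))
  sdv <- unname(apply(trace, 2, stats::sd))
  mn <- unname(apply(trace, 2, min))
  mx <- unname(apply(trace, 2, max))
  bands <- tibble::tibble(group = group, output = output, pct = pct,
                          mean = mu, sd = sdv, min = mn, max = mx,
                          range = mx - mn)
  summary <- dplyr::summarise(
    dplyr::group_by(bands, .data$group, .data$output),
    mean_sd = mean(.data$sd), max_sd = max(.data$sd),
    mean_range = mean(.data$range), max_range = max(.data$range),
    .groups = "drop")
  structure(list(bands = bands, summary = summary,
                 n_trials = length(ok)), class = "msk_bands")
}

#' Input-output correlation analysis
#'
#' For every (output, input variable, stance percent) cell, the coefficient
#' of determination R-squared of the simple linear regression of the output
#' on the input across successful trials (equal to the squared Pearson
#' correlation), with the two-sided p-value of the correlation t-test on
#' n - 2 degrees of freedom. Cells with zero-variance input or output are
#' undefined and masked out.
#'
#' @param ensemble an `msk_ensemble`
#' @param groups which output groups to correlate (default `"contact"`,
#'   the joint contact forces)
#' @return an `msk_correlation`: list with `r2` and `p` (matrices inputs x
#'   output-cells), `masked`, `inputs`, `output_names`, `n`
#' @export
correlate <- function(ensemble, groups = "contact") {
  ok <- which(ensemble$success)
  if (length(ok) < 10) stop("mskuq_too_few_trials: need >= 10 successful trials", call. = FALSE)
  # trace rows correspond to the successful trials, in order
  X <- ensemble$samples$values[ok, , drop = FALSE]
  sel <- grepl(paste0("^(", paste(groups, collapse = "|"), "):"),
               ensemble$output_names)
  Y <- ensemble$trace[, sel, drop = FALSE]
  stopifnot(nrow(Y) == length(ok))
  n <- length(ok)
  sx <- apply(X, 2, stats::sd); sy <- apply(Y, 2, stats::sd)
  Xo <- X; Yo <- Y
  Xo[, sx == 0] <- NA; Yo[, sy == 0] <- NA
  r <- suppressWarnings(stats::cor(Xo, Yo))
  masked <- !is.finite(r)
  r[masked] <- NA
  r2 <- r^2
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, 1e-300))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  structure(list(r2 = r2, p = p, masked = masked,
                 inputs = colnames(X), output_names = colnames(Y), n = n),
            class = "msk_correlation")
}

#' Summarize significant correlations
#'
#' Fractions of (output, input, stance percent) cells with significant
#' R-squared, with significant R-squared above `r2_lo`, the maximum
#' significant R-squared, and the distinct input variables involved above
#' `r2_lo`. Because the denominator convention behind such percentages can
#' be counted per cell or per input variable, both are reported, labelled.
#'
#' @param report an `msk_correlation`
#' @param p_thr significance threshold (default 0.001)
#' @param r2_lo,r2_hi reporting thresholds (defaults 0.2 and 0.7)
#' @return list with `frac_cells_significant`, `frac_cells_above_lo`,
#'   `frac_inputs_significant`, `frac_inputs_above_lo`, `max_significant_r2`,
#'   `any_above_hi`, `involved_inputs`, `n_cells`
#' @export
significance_summary <- function(report, p_thr = 0.001, r2_lo = 0.2,
                                 r2_hi = 0.7) {
  valid <- !report$masked
  sig <- valid & (report$p < p_thr)
  above <- sig & (report$r2 > r2_lo)
  n_cells <- sum(valid)
  inputs_sig <- rowSums(sig, na.rm = TRUE) > 0
  inputs_above <- rowSums(above, na.rm = TRUE) > 0
  list(
    frac_cells_significant = sum(sig, na.rm = TRUE) / n_cells,
    frac_cells_above_lo = sum(above, na.rm = TRUE) / n_cells,
    frac_inputs_significant = mean(inputs_sig),
    frac_inputs_above_lo = mean(inputs_above),
    max_significant_r2 = if (any(sig, na.rm = TRUE)) max(report$r2[sig], na.rm = TRUE) else NA_real_,
    any_above_hi = any(sig & report$r2 > r2_hi, na.rm = TRUE),
    involved_inputs = report$inputs[inputs_above],
    n_cells = n_cells)
}

# --- broom-style and plotting methods ---------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-stance-percent bands of an ensemble
#' @param x an `msk_ensemble`
#' @param ... unused
#' @method tidy msk_ensemble
#' @export
tidy.msk_ensemble <- function(x, ...) {
  ensemble_bands(x)$bands
}

#' One-row summary of an ensemble
#' @param x an `msk_ensemble`
#' @param ... unused
#' @method glance msk_ensemble
#' @export
glance.msk_ensemble <- function(x, ...) {
  b <- ensemble_bands(x)
  contact <- dplyr::filter(b$summary, .data$group == "contact")
  muscle <- dplyr::filter(b$summary, .data$group == "muscle")
  tibble::tibble(
    n_trials = length(x$success),
    n_success = sum(x$success),
    pct_unsuccessful = 100 * mean(!x$success),
    converged = if (!is.null(x$convergence)) x$convergence$converged else NA,
    max_sd_contact_bw = max(contact$max_sd),
    max_range_contact_bw = max(contact$max_range),
    max_sd_muscle_bw = max(muscle$max_sd),
    max_range_muscle_bw = max(muscle$max_range))
}

#' @method tidy msk_bands
#' @export
tidy.msk_bands <- function(x, ...) x$bands

#' @method glance msk_bands
#' @export
glance.msk_bands <- function(x, ...) x$summary

#' Tidy correlation report
#' @param x an `msk_correlation`
#' @param ... unused
#' @method tidy msk_correlation
#' @export
tidy.msk_correlation <- function(x, ...) {
  parts <- strsplit(x$output_names, ":", fixed = TRUE)
  out <- vapply(parts, `[[`, "", 2)
  frame <- as.integer(vapply(parts, `[[`, "", 3))
  npts <- max(frame)
  tibble::tibble(
    input = rep(x$inputs, times = ncol(x$r2)),
    output = rep(out, each = nrow(x$r2)),
    pct = rep((frame - 1) / (npts - 1) * 100, each = nrow(x$r2)),
    r2 = as.vector(x$r2),
    p = as.vector(x$p))
}

#' Mean +/- SD band plot of ensemble outputs
#'
#' @param object an `msk_bands`
#' @param group output group to plot (`"contact"`, `"muscle"`, `"moment"`,
#'   `"angle"`)
#' @param ... unused
#' @method autoplot msk_bands
#' @export
autoplot.msk_bands <- function(object, group = "contact", ...) {
  d <- dplyr::filter(object$bands, .data$group == !!group)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(x = "stance (%)",
                  y = if (group %in% c("contact", "muscle")) "force (BW)"
                      else if (group == "moment") "moment (N m)"
                      else "angle (deg)")
}

#' R-squared versus stance curves for inputs passing the reporting threshold
#'
#' @param object an `msk_correlation`
#' @param p_thr,r2_lo thresholds (defaults 0.001 and 0.2)
#' @param ... unused
#' @method autoplot msk_correlation
#' @export
autoplot.msk_correlation <- function(object, p_thr = 0.001, r2_lo = 0.2, ...) {
  d <- tidy.msk_correlation(object)
  keep <- dplyr::filter(d, .data$p < p_thr, .data$r2 > r2_lo)
  sel <- dplyr::distinct(keep, .data$input, .data$output)
  d2 <- dplyr::semi_join(d, sel, by = c("input", "output"))
  d2 <- dplyr::mutate(d2, r2 = ifelse(.data$p < p_thr, .data$r2, NA_real_))
  ggplot2::ggplot(d2, ggplot2::aes(x = .data$pct, y = .data$r2,
                                   color = .data$input)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(x = "stance (%)", y = expression(R^2))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
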