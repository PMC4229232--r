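# Uncertainty engine: the three categories of stochastic input variables
# (body landmark positions, musculotendon point positions, maximum muscle
# tension), attachment-area plane/line fitting, Latin hypercube sampling
# and instantiation of perturbed models.

#' Fit a plane or line to an attachment-area point set
#'
#' Principal-axes fit of the point cloud. If the ratio of the first to the
#' second principal extent is at least `lw_ratio_threshold` the area is
#' treated as elongated and approximated by a line (one perturbation
#' direction); otherwise by a plane (two directions).
#'
#' @param points n x 3 matrix of points (m)
#' @param lw_ratio_threshold length/width ratio above which the fit
#'   degenerates to a line (default 3)
#' @return list with `mode` ("plane" or "line"), `basis` (3 x 1 or 3 x 2
#'   orthonormal directions), `normal` (plane mode), `centroid`, `extents`
#'   (principal SDs)
#' @export
fit_attachment_frame <- function(points, lw_ratio_threshold = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  centroid <- colMeans(points)
  pc <- sweep(points, 2, centroid)
  if (max(abs(pc)) < 1e-12) {
    stop("mskuq_degenerate_attachment: all points coincident", call. = FALSE)
  }
  if (n < 2) stop("mskuq_degenerate_attachment: need >= 2 points", call. = FALSE)
  S <- crossprod(pc) / n
  eg <- eigen(S, symmetric = TRUE)
  ext <- sqrt(pmax(eg$values, 0))
  mode <- if (ext[2] < 1e-12 || ext[1] / max(ext[2], 1e-300) >= lw_ratio_threshold) {
    "line"
  } else "plane"
  if (mode == "plane" && n < 3) {
    stop("mskuq_degenerate_attachment: plane fit needs >= 3 points", call. = FALSE)
  }
  basis <- if (mode == "line") eg$vectors[, 1, drop = FALSE] else eg$vectors[, 1:2]
  list(mode = mode, basis = basis,
       normal = if (mode == "plane") eg$vectors[, 3] else NULL,
       centroid = centroid, extents = ext)
}

#' Packaged landmark-position standard deviations
#'
#' Inter-operator virtual-palpation SDs (mm) for the 21 standard landmarks,
#' in the antero-posterior (x), cranio-caudal (y) and medio-lateral (z)
#' directions of the body reference frames.
#'
#' @return tibble with columns `landmark`, `sd_x_mm`, `sd_y_mm`, `sd_z_mm`
#' @export
landmark_sd_table <- function() {
  path <- system.file("extdata", "landmark_sd.csv", package = "mskuq")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Define the stochastic input variables of a model
#'
#' Category 1: the three body-frame coordinates of every landmark, normal
#' with the packaged per-landmark SDs (left-side landmarks mirror the
#' right-side values). Category 2: musculotendon point positions — origins
#' and insertions perturbed within their fitted attachment plane (2
#' directions) or along the fitted line (1 direction), pseudo-origins and
#' pseudo-insertions along the three host-body axes; all normal with SD
#' `point_sd_mm`. Category 3: one maximum-muscle-tension variable, uniform
#' over `sigma_range`. The realized variable count is whatever the model
#' yields; it is reported, never assumed.
#'
#' @param model an `msk_model`
#' @param landmark_sd optional SD table (default [landmark_sd_table()])
#' @param point_sd_mm SD of musculotendon point perturbations, mm
#' @param sigma_range uniform range of maximum muscle tension, N/cm^2
#' @param lw_ratio_threshold see [fit_attachment_frame()]
#' @return tibble of variables: `id`, `category`, `dist`, `mean`, `sd`,
#'   `lo`, `hi`, `units`, target columns and a `basis` list-column holding
#'   the world perturbation direction of each variable
#' @export
define_stochastic_variables <- function(model, landmark_sd = landmark_sd_table(),
                                        point_sd_mm = 5,
                                        sigma_range = c(35, 137),
                                        lw_ratio_threshold = 3) {
  rows <- list()
  axes <- c("x", "y", "z")
  for (seg in names(model$segments)) {
    sdef <- model$segments[[seg]]
    lms <- rownames(sdef$landmarks_body)
    for (nm in lms) {
      key <- nm
      if (!key %in% landmark_sd$landmark && grepl("^L", key)) {
        key <- sub("^L", "R", key)  # mirror left-side landmarks
      }
      i <- match(key, landmark_sd$landmark)
      if (is.na(i)) {
        stop("mskuq_missing_sd: no SD entry for landmark ", nm, call. = FALSE)
      }
      sds <- c(landmark_sd$sd_x_mm[i], landmark_sd$sd_y_mm[i],
               landmark_sd$sd_z_mm[i]) / 1000
      for (a in 1:3) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = paste0("lm:", nm, ":", axes[a]), category = "landmark",
          dist = "normal", mean = 0, sd = sds[a], lo = NA_real_, hi = NA_real_,
          units = "m", landmark = nm, segment = seg, axis = axes[a],
          mtu = NA_character_, point_index = NA_integer_,
          basis = list(sdef$frame0$R[, a]))
      }
    }
  }
  for (mn in names(model$mtus)) {
    m <- model$mtus[[mn]]
    for (p in seq_along(m$path)) {
      role <- m$path[[p]]$role
      host <- m$path[[p]]$body
      if (role %in% c("origin", "insertion")) {
        cloud <- m$attachments[[as.character(p)]]
        if (is.null(cloud)) next
        fr <- fit_attachment_frame(cloud, lw_ratio_threshold)
        for (k in seq_len(ncol(fr$basis))) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = paste0("mtu:", mn, ":", p, ":", fr$mode, k),
            category = "mtu_point", dist = "normal", mean = 0,
            sd = point_sd_mm / 1000, lo = NA_real_, hi = NA_real_,
            units = "m", landmark = NA_character_, segment = host,
            axis = NA_character_, mtu = mn, point_index = p,
            basis = list(fr$basis[, k]))
        }
      } else if (role %in% c("pseudo_origin", "pseudo_insertion")) {
        R0 <- model$segments[[host]]$frame0$R
        for (a in 1:3) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = paste0("mtu:", mn, ":", p, ":", axes[a]),
            category = "mtu_point", dist = "normal", mean = 0,
            sd = point_sd_mm / 1000, lo = NA_real_, hi = NA_real_,
            units = "m", landmark = NA_character_, segment = host,
            axis = axes[a], mtu = mn, point_index = p, basis = list(R0[, a]))
        }
      }
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    id = "sigma", category = "sigma", dist = "uniform",
    mean = NA_real_, sd = NA_real_, lo = sigma_range[1], hi = sigma_range[2],
    units = "N/cm^2", landmark = NA_character_, segment = NA_character_,
    axis = NA_character_, mtu = NA_character_, point_index = NA_integer_,
    basis = list(NULL))
  vars <- dplyr::bind_rows(rows)
  message("mskuq: defined ", nrow(vars), " stochastic input variables (",
          sum(vars$category == "landmark"), " landmark, ",
          sum(vars$category == "mtu_point"), " musculotendon point, ",
          sum(vars$category == "sigma"), " tension)")
  vars
}

#' Latin hypercube sample of the stochastic variables
#'
#' Stratified sampling: for each variable, one draw in each of N
#' equal-probability strata, randomly paired across variables;
#' reproducible under a fixed seed.
#'
#' @param variables tibble from [define_stochastic_variables()]
#' @param N number of samples
#' @param seed integer seed
#' @return object of class `msk_samples`: list with `values`
#'   (N x n_variables matrix, columns named by variable id), `variables`,
#'   `seed`, `method`
#' @export
lhs_sample <- function(variables, N, seed = 1) {
  stopifnot(N >= 1)
  nv <- nrow(variables)
  set.seed(seed)
  U <- lhs::randomLHS(N, nv)
  vals <- matrix(0, N, nv, dimnames = list(NULL, variables$id))
  for (j in seq_len(nv)) {
    vals[, j] <- switch(variables$dist[j],
      normal = stats::qnorm(U[, j], variables$mean[j], variables$sd[j]),
      uniform = stats::qunif(U[, j], variables$lo[j], variables$hi[j]),
      stop("mskuq_unknown_distribution: ", variables$dist[j], call. = FALSE))
  }
  structure(list(values = vals, variables = variables, seed = seed,
                 method = "LHS"),
            class = "msk_samples")
}

#' Instantiate a perturbed model from one sample row
#'
#' Applies landmark offsets in the baseline body frames (so frames, joints,
#' inertia and kinematics are all rebuilt from the perturbed cloud),
#' displaces musculotendon points within their attachment plane/line or
#' along the host-body axes, sets the sampled maximum muscle tension, and
#' recompiles the model. The baseline is untouched.
#'
#' @param baseline the baseline `msk_model`
#' @param variables tibble from [define_stochastic_variables()]
#' @param row named numeric vector (one row of the sample matrix)
#' @return a new `msk_model`
#' @export
instantiate_model <- function(baseline, variables, row) {
  build_model(perturb_definition(baseline, variables, row))
}

# apply one sample row to the model definition (no rebuild); the cheap,
# purely-geometric half of instantiate_model
perturb_definition <- function(baseline, variables, row) {
  def <- baseline$definition
  vals <- row[variables$id]
  if (any(is.na(vals))) {
    stop("mskuq_sample_mismatch: sample row does not cover all variables",
         call. = FALSE)
  }
  lm <- def$landmarks
  is_lm <- variables$category == "landmark"
  if (any(is_lm)) {
    idx <- which(is_lm)
    for (k in idx) {
      i <- match(variables$landmark[k], lm$name)
      off <- variables$basis[[k]] * vals[k]
      lm$x[i] <- lm$x[i] + off[1]
      lm$y[i] <- lm$y[i] + off[2]
      lm$z[i] <- lm$z[i] + off[3]
    }
  }
  def$landmarks <- lm
  is_mp <- variables$category == "mtu_point"
  if (any(is_mp)) {
    mtu_index <- stats::setNames(seq_along(def$mtus),
                                 vapply(def$mtus, `[[`, "", "name"))
    for (k in which(is_mp)) {
      mi <- mtu_index[[variables$mtu[k]]]
      p <- variables$point_index[k]
      def$mtus[[mi]]$path[[p]]$pos <- def$mtus[[mi]]$path[[p]]$pos +
        variables$basis[[k]] * vals[k]
    }
  }
  if ("sigma" %in% variables$category) {
    def$sigma <- unname(vals[which(variables$category == "sigma")[1]])
  }
  def
}
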