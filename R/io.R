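# File formats: TRC marker trajectories, MOT/STO time series, the JSON
# model schema, and the on-disk ensemble store (directory of CSV/JSON).

#' Read a TRC marker-trajectory file
#'
#' @param path file path
#' @return list with `time` (s), `names`, `xyz` (frames x markers x 3, m),
#'   `rate` (Hz), `units` (original units string)
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5) stop("mskuq_malformed_trc: file too short (line 1)", call. = FALSE)
  hk <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hv <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% hk)) {
    stop("mskuq_malformed_trc: missing header keys (line 2)", call. = FALSE)
  }
  geth <- function(k) hv[match(k, hk)]
  rate <- as.numeric(geth("DataRate"))
  nfr <- as.integer(geth("NumFrames"))
  nmk <- as.integer(geth("NumMarkers"))
  units <- geth("Units")
  mk_line <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  names_mk <- mk_line[mk_line != "" & !mk_line %in% c("Frame#", "Time")]
  if (length(names_mk) != nmk) {
    stop("mskuq_malformed_trc: marker-name count mismatch (line 4)", call. = FALSE)
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nfr) {
    stop("mskuq_malformed_trc: data row count != NumFrames (line 6)", call. = FALSE)
  }
  scale <- if (tolower(units) == "mm") 1 / 1000 else 1
  time <- numeric(nfr)
  xyz <- array(NA_real_, dim = c(nfr, nmk, 3))
  for (i in seq_len(nfr)) {
    v <- as.numeric(strsplit(data_lines[i], "\t", fixed = TRUE)[[1]])
    if (length(v) != 2 + 3 * nmk) {
      stop("mskuq_malformed_trc: ragged data row (line ", 5 + i, ")", call. = FALSE)
    }
    time[i] <- v[2]
    xyz[i, , ] <- matrix(v[-(1:2)], nmk, 3, byrow = TRUE) * scale
  }
  list(time = time, names = names_mk, xyz = xyz, rate = rate, units = units)
}

#' Write a TRC marker-trajectory file
#'
#' @param markers list with `time`, `names`, `xyz` (m)
#' @param path output path
#' @param units `"mm"` (default) or `"m"`
#' @export
write_trc <- function(markers, path, units = "mm") {
  time <- markers$time
  nfr <- length(time); nmk <- length(markers$names)
  rate <- if (nfr > 1) 1 / (time[2] - time[1]) else 1
  scale <- if (units == "mm") 1000 else 1
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(fmt(rate), fmt(rate), nfr, nmk, units, fmt(rate), 1, nfr,
                   sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(markers$names, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), nmk),
                                    rep(seq_len(nmk), each = 3))),
                   collapse = "\t"), con)
  for (i in seq_len(nfr)) {
    row <- as.vector(t(markers$xyz[i, , ])) * scale
    writeLines(paste(c(i, fmt(time[i]), fmt(row)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a MOT/STO tab-delimited time-series file
#'
#' @param path file path
#' @return tibble, first column `time`
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  eh <- which(trimws(lines) == "endheader")
  if (length(eh) == 0) stop("mskuq_malformed_mot: no endheader line", call. = FALSE)
  eh <- eh[1]
  cols <- strsplit(lines[eh + 1], "\t", fixed = TRUE)[[1]]
  if (!"time" %in% cols) stop("mskuq_malformed_mot: no time column", call. = FALSE)
  data_lines <- lines[-(1:(eh + 1))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0) stop("mskuq_malformed_mot: empty data section", call. = FALSE)
  M <- matrix(NA_real_, length(data_lines), length(cols))
  for (i in seq_along(data_lines)) {
    v <- as.numeric(strsplit(data_lines[i], "\t", fixed = TRUE)[[1]])
    if (length(v) != length(cols)) {
      stop("mskuq_malformed_mot: ragged row (line ", eh + 1 + i, ")", call. = FALSE)
    }
    M[i, ] <- v
  }
  colnames(M) <- cols
  tibble::as_tibble(M)
}

#' Write a MOT/STO tab-delimited time-series file
#'
#' @param table data frame with a `time` column
#' @param path output path
#' @param name header name line
#' @export
write_mot <- function(table, path, name = basename(path)) {
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(name, con)
  writeLines(paste0("nRows=", nrow(table)), con)
  writeLines(paste0("nColumns=", ncol(table)), con)
  writeLines("endheader", con)
  writeLines(paste(colnames(table), collapse = "\t"), con)
  for (i in seq_len(nrow(table))) {
    writeLines(paste(fmt(as.numeric(table[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

# --- model JSON schema ------------------------------------------------------

#' Serialize a model definition to JSON
#'
#' The JSON schema stores the buildable definition (landmark cloud, muscle
#' paths and attachment areas, architecture parameters, densities, mass
#' fractions, sigma); reading rebuilds the compiled model, so the
#' round-trip is lossless.
#'
#' @param model an `msk_model`
#' @param path output path
#' @export
write_model_json <- function(model, path) {
  def <- model$definition
  def$mtus <- lapply(def$mtus, function(m) {
    m$attachments <- lapply(m$attachments, function(a) unclass(as.data.frame(a)))
    m
  })
  def$landmarks <- as.list(as.data.frame(def$landmarks))
  def$densities <- as.list(def$densities)          # keep names as JSON keys
  def$mass_fractions <- as.list(def$mass_fractions)
  jsonlite::write_json(def, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model definition from JSON and build the model
#'
#' @param path JSON path
#' @return an `msk_model`
#' @export
read_model_json <- function(path) {
  def <- jsonlite::read_json(path, simplifyVector = FALSE)
  def$landmarks <- tibble::tibble(
    segment = unlist(def$landmarks$segment),
    name = unlist(def$landmarks$name),
    x = unlist(def$landmarks$x), y = unlist(def$landmarks$y),
    z = unlist(def$landmarks$z))
  def$mass_fractions <- unlist(def$mass_fractions)
  def$densities <- unlist(def$densities)
  def$mtus <- lapply(def$mtus, function(m) {
    m$path <- lapply(m$path, function(pp) {
      list(body = pp$body, role = pp$role, pos = as.numeric(unlist(pp$pos)))
    })
    m$attachments <- lapply(m$attachments, function(a) {
      A <- do.call(cbind, lapply(a, function(col) as.numeric(unlist(col))))
      dimnames(A) <- NULL
      A
    })
    m$Vol <- as.numeric(m$Vol); m$l_o_g <- as.numeric(m$l_o_g)
    m$L_mt_g <- as.numeric(m$L_mt_g)
    m
  })
  build_model(def)
}

# --- ensemble store ---------------------------------------------------------

#' Save an ensemble to a directory of CSV/JSON files
#'
#' @param ensemble an `msk_ensemble`
#' @param dir output directory (created)
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ensemble$samples$values,
                   file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(data.frame(success = ensemble$success,
                              reason = ensemble$reasons),
                   file.path(dir, "status.csv"), row.names = FALSE)
  tr <- ensemble$trace
  utils::write.csv(tr, file.path(dir, "trace.csv"), row.names = FALSE)
  jsonlite::write_json(list(config = ensemble$config,
                            output_names = ensemble$output_names,
                            body_weight = ensemble$body_weight,
                            seed = ensemble$samples$seed),
                       file.path(dir, "meta.json"),
                       digits = NA, auto_unbox = TRUE)
  vars <- ensemble$samples$variables
  vars$basis <- NULL
  utils::write.csv(as.data.frame(vars), file.path(dir, "variables.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load an ensemble saved with [save_ensemble()]
#'
#' Restores everything the statistics stages need (trace, samples, success
#' mask, configuration).
#'
#' @param dir directory path
#' @return an `msk_ensemble`
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  samples <- as.matrix(utils::read.csv(file.path(dir, "samples.csv"),
                                       check.names = FALSE))
  status <- utils::read.csv(file.path(dir, "status.csv"))
  trace <- as.matrix(utils::read.csv(file.path(dir, "trace.csv"),
                                     check.names = FALSE))
  colnames(trace) <- meta$output_names
  cfg <- do.call(run_config, meta$config)
  structure(list(outputs = NULL,
                 samples = list(values = samples, variables = NULL,
                                seed = meta$seed, method = "LHS"),
                 success = status$success, reasons = status$reason,
                 trace = trace, convergence = NULL, config = cfg,
                 output_names = meta$output_names,
                 body_weight = meta$body_weight),
            class = "msk_ensemble")
}
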