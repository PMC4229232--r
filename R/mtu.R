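# Musculotendon path geometry: lengths, moment arms, maximum isometric force.

mtu_length_state <- function(model, st, mtu) {
  L <- 0
  prev <- NULL
  for (pp in mtu$path) {
    w <- pose_apply(st$poses[[pp$body]], pp$pos_body)
    if (!is.null(prev)) L <- L + vnorm(w - prev)
    prev <- w
  }
  L
}

#' Musculotendon length at a configuration
#'
#' Sum of Euclidean distances between consecutive path points (line-segment
#' actuator representation, no wrapping surfaces).
#'
#' @param model an `msk_model`
#' @param q coordinate vector
#' @param mtu MTU name (character) or an MTU element of `model$mtus`
#' @return length in meters
#' @export
mtu_length <- function(model, q, mtu) {
  if (is.character(mtu)) mtu <- model$mtus[[mtu]]
  mtu_length_state(model, fk_state(model, q), mtu)
}

#' Tendon-excursion moment arms
#'
#' Moment arm of each musculotendon unit about each articulated coordinate,
#' defined as minus the partial derivative of musculotendon length with
#' respect to the coordinate. Computed analytically from the geometric
#' Jacobian of the path points; a central-difference variant is available
#' via `method = "fd"` and serves as an independent numerical route.
#'
#' @param model an `msk_model`
#' @param q coordinate vector
#' @param mtus character vector of MTU names (default all)
#' @param method `"analytic"` (default) or `"fd"` (central differences)
#' @param h finite-difference step in radians for `method = "fd"`
#' @return matrix (MTUs x articulated coordinates), meters
#' @export
moment_arms <- function(model, q, mtus = names(model$mtus),
                        method = c("analytic", "fd"), h = 1e-6) {
  method <- match.arg(method)
  art <- which(model$articulated)
  r <- matrix(0, length(mtus), length(art),
              dimnames = list(mtus, model$coord_names[art]))
  if (method == "fd") {
    for (k in seq_along(art)) {
      qp <- q; qm <- q
      qp[art[k]] <- qp[art[k]] + h
      qm[art[k]] <- qm[art[k]] - h
      stp <- fk_state(model, qp); stm <- fk_state(model, qm)
      for (i in seq_along(mtus)) {
        m <- model$mtus[[mtus[i]]]
        r[i, k] <- -(mtu_length_state(model, stp, m) -
                     mtu_length_state(model, stm, m)) / (2 * h)
      }
    }
    return(r)
  }
  st <- fk_state(model, q)
  for (i in seq_along(mtus)) {
    m <- model$mtus[[mtus[i]]]
    np <- length(m$path)
    pw <- matrix(0, 3, np)
    for (p in seq_len(np)) {
      pw[, p] <- pose_apply(st$poses[[m$path[[p]]$body]], m$path[[p]]$pos_body)
    }
    dL <- numeric(length(model$coord_names))
    for (p in seq_len(np - 1L)) {
      d <- pw[, p + 1L] - pw[, p]
      nd <- vnorm(d)
      if (nd < 1e-12) next
      u <- d / nd
      b1 <- m$path[[p]]$body; b2 <- m$path[[p + 1L]]$body
      if (b1 == b2) next  # rigid within one body: no excursion
      for (k in union(chain_coords(model, b1), chain_coords(model, b2))) {
        J1 <- if (k %in% chain_coords(model, b1)) {
          if (st$type_tr[k]) st$axis_w[, k] else cross3(st$axis_w[, k], pw[, p] - st$point_w[, k])
        } else c(0, 0, 0)
        J2 <- if (k %in% chain_coords(model, b2)) {
          if (st$type_tr[k]) st$axis_w[, k] else cross3(st$axis_w[, k], pw[, p + 1L] - st$point_w[, k])
        } else c(0, 0, 0)
        dL[k] <- dL[k] + sum(u * (J2 - J1))
      }
    }
    r[i, ] <- -dL[art]
  }
  r
}

#' Maximum isometric force from muscle volume and length scaling
#'
#' Subject optimal fiber length is assumed proportional to musculotendon
#' length: `l_o_s = l_o_g * (L_mt_s / L_mt_g)`. PCSA is `Vol / l_o_s`
#' (cm^2) and `Fmax = PCSA * sigma` with sigma in N/cm^2.
#'
#' @param Vol muscle volume, cm^3
#' @param l_o_g generic optimal fiber length, cm
#' @param L_mt_g generic musculotendon length, cm
#' @param L_mt_s subject musculotendon length, cm
#' @param sigma maximum muscle tension, N/cm^2 (baseline 61)
#' @return maximum isometric force, N
#' @export
estimate_fmax <- function(Vol, l_o_g, L_mt_g, L_mt_s, sigma = 61) {
  vals <- c(Vol = Vol, l_o_g = l_o_g, L_mt_g = L_mt_g, L_mt_s = L_mt_s,
            sigma = sigma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("mskuq_invalid_fmax_input: all inputs must be positive and finite",
         call. = FALSE)
  }
  l_o_s <- l_o_g * (L_mt_s / L_mt_g)
  (Vol / l_o_s) * sigma
}
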