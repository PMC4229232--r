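# Anatomical body frames from landmark positions.
#
# Frame conventions (ISB-style, consistent across both sides): x anterior,
# y cranial (proximal), z to the subject's right. Left-side recipes use the
# medial/lateral landmark pairs swapped so that z keeps its global sense.

required_landmarks <- function(segment) {
  switch(segment,
    pelvis  = c("RASIS", "LASIS", "RPSIS", "LPSIS"),
    thigh_r = c("RHC", "RME", "RLE"),
    thigh_l = c("LHC", "LME", "LLE"),
    shank_r = c("RMC", "RLC", "RMM", "RLM"),
    shank_l = c("LMC", "LLC", "LMM", "LLM"),
    foot_r  = c("RCA", "RFM", "RVM"),
    foot_l  = c("LCA", "LFM", "LVM"),
    stop("mskuq_unknown_segment: ", segment, call. = FALSE)
  )
}

#' Construct anatomical body frames from landmark positions
#'
#' Builds one orthonormal reference frame per segment from the world (or
#' calibration-pose) positions of its anatomical landmarks, following
#' ISB-style axis recipes: x anterior, y cranial, z to the subject's right.
#' The pelvis frame originates at the midpoint of the anterior superior iliac
#' spines with z along the inter-ASIS line; thigh frames run from the hip
#' centre to the mid-epicondyle point; shank frames from the mid-malleolus to
#' the mid-condyle point; foot frames from the calcaneus towards the
#' metatarsal heads.
#'
#' @param landmarks data frame with columns `segment`, `name`, `x`, `y`, `z`
#'   (positions in meters).
#' @param segments character vector of segments to build; default all
#'   segments present in `landmarks`.
#' @return named list of poses, each `list(R, p)` with `R` an orthonormal
#'   3x3 rotation (columns = world directions of the body x/y/z axes) and
#'   `p` the frame origin.
#' @export
build_body_frames <- function(landmarks, segments = unique(landmarks$segment)) {
  lm_pos <- function(nm) {
    i <- match(nm, landmarks$name)
    if (is.na(i)) {
      stop("mskuq_missing_landmark: required landmark '", nm, "' not found",
           call. = FALSE)
    }
    c(landmarks$x[i], landmarks$y[i], landmarks$z[i])
  }
  frames <- list()
  for (seg in segments) {
    req <- required_landmarks(seg)
    for (nm in req) lm_pos(nm)  # presence check with named error
    frames[[seg]] <- switch(sub("_(r|l)$", "", seg),
      pelvis = {
        rasis <- lm_pos("RASIS"); lasis <- lm_pos("LASIS")
        mid_asis <- (rasis + lasis) / 2
        mid_psis <- (lm_pos("RPSIS") + lm_pos("LPSIS")) / 2
        z <- rasis - lasis
        R <- frame_from_axes(z, "z", mid_asis - mid_psis, "x")
        list(R = R, p = mid_asis)
      },
      thigh = {
        side <- if (grepl("_r$", seg)) "R" else "L"
        hc <- lm_pos(paste0(side, "HC"))
        me <- lm_pos(paste0(side, "ME")); le <- lm_pos(paste0(side, "LE"))
        y <- hc - (me + le) / 2
        zt <- if (side == "R") le - me else me - le
        R <- frame_from_axes(y, "y", cross3(y, zt), "x")
        list(R = R, p = hc)
      },
      shank = {
        side <- if (grepl("_r$", seg)) "R" else "L"
        mc <- lm_pos(paste0(side, "MC")); lc <- lm_pos(paste0(side, "LC"))
        mm <- lm_pos(paste0(side, "MM")); lm <- lm_pos(paste0(side, "LM"))
        ko <- (mc + lc) / 2
        y <- ko - (mm + lm) / 2
        zt <- if (side == "R") lc - mc else mc - lc
        R <- frame_from_axes(y, "y", cross3(y, zt), "x")
        list(R = R, p = ko)
      },
      foot = {
        side <- if (grepl("_r$", seg)) "R" else "L"
        ca <- lm_pos(paste0(side, "CA"))
        fm <- lm_pos(paste0(side, "FM")); vm <- lm_pos(paste0(side, "VM"))
        x <- (fm + vm) / 2 - ca
        up <- if (side == "R") cross3(vm - ca, fm - ca) else cross3(fm - ca, vm - ca)
        R <- frame_from_axes(x, "x", up, "y")
        list(R = R, p = ca)
      },
      stop("mskuq_unknown_segment: ", seg, call. = FALSE)
    )
  }
  frames
}
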