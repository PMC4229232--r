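# Articulated musculoskeletal model: construction from a definition
# (landmark cloud + musculotendon description) and forward kinematics.
#
# A model definition is declarative: a calibration landmark cloud in world
# coordinates, musculotendon paths (world calibration coordinates + host
# bodies + point roles), attachment-area point clouds, muscle architecture
# parameters, mass distribution rules and the maximum muscle tension sigma.
# build_model() compiles it into frames, joints, inertia and Fmax values, so
# that perturbing the definition and rebuilding propagates uncertainty to
# every derived quantity.

GRAVITY <- 9.80665  # m/s^2

BODY_ORDER <- c("pelvis", "thigh_r", "shank_r", "foot_r",
                "thigh_l", "shank_l", "foot_l")

#' Compile a model definition into an articulated musculoskeletal model
#'
#' Builds body frames from the landmark cloud, derives joint centres and
#' hinge axes from the anatomical landmarks (hip centre landmark, trans-
#' epicondylar knee axis, trans-malleolar ankle axis), sizes the two-density
#' segment geometry from landmark distances, and computes each
#' musculotendon unit's neutral-pose length and maximum isometric force
#' (PCSA times sigma, with subject fiber length scaled in proportion to
#' musculotendon length).
#'
#' @param definition model definition list, as produced by
#'   [generate_template_model()] (see that function for the schema).
#' @return an object of class `msk_model`.
#' @export
build_model <- function(definition) {
  def <- definition
  lms <- def$landmarks
  frames <- build_body_frames(lms, BODY_ORDER)

  lm_world <- function(nm) {
    i <- match(nm, lms$name)
    if (is.na(i)) stop("mskuq_missing_landmark: ", nm, call. = FALSE)
    c(lms$x[i], lms$y[i], lms$z[i])
  }

  # landmarks in body frames
  segments <- list()
  for (seg in BODY_ORDER) {
    rows <- which(lms$segment == seg)
    pb <- matrix(0, length(rows), 3)
    for (k in seq_along(rows)) {
      pb[k, ] <- pose_invert_apply(frames[[seg]],
                                   c(lms$x[rows[k]], lms$y[rows[k]], lms$z[rows[k]]))
    }
    rownames(pb) <- lms$name[rows]
    segments[[seg]] <- list(name = seg, frame0 = frames[[seg]],
                            landmarks_body = pb)
  }

  # joint centres / axes from landmarks (world, calibration pose)
  jc <- list(
    hip_r = lm_world("RHC"), hip_l = lm_world("LHC"),
    knee_r = (lm_world("RME") + lm_world("RLE")) / 2,
    knee_l = (lm_world("LME") + lm_world("LLE")) / 2,
    ankle_r = (lm_world("RMM") + lm_world("RLM")) / 2,
    ankle_l = (lm_world("LMM") + lm_world("LLM")) / 2
  )
  jax <- list(
    knee_r = unitv(lm_world("RLE") - lm_world("RME"), "knee axis"),
    knee_l = unitv(lm_world("LME") - lm_world("LLE"), "knee axis"),
    ankle_r = unitv(lm_world("RLM") - lm_world("RMM"), "ankle axis"),
    ankle_l = unitv(lm_world("LMM") - lm_world("LLM"), "ankle axis")
  )

  # segment geometry + inertia from landmark-derived dimensions
  total_mass <- def$mass
  mf <- def$mass_fractions
  bvf <- def$bone_volume_fraction %||% 0.15
  dens <- def$densities %||% default_densities()
  for (seg in BODY_ORDER) {
    geom <- build_segment_geometry(seg, frames, jc, lm_world,
                                   total_mass * mf[[sub("_(r|l)$", "", seg)]],
                                   bvf, dens)
    ip <- compute_inertial_properties(geom)
    segments[[seg]]$geometry <- geom
    segments[[seg]]$mass <- ip$mass
    segments[[seg]]$com <- ip$com
    segments[[seg]]$inertia <- ip$inertia
  }

  # kinematic tree: joints in tree order, coordinates flattened
  ground_axes <- diag(3)
  joints <- list()
  add_joint <- function(joints, name, parent, child, center_w, dofs) {
    if (parent == "ground") {
      loc_p <- center_w
      R_p0 <- diag(3)
    } else {
      loc_p <- pose_invert_apply(frames[[parent]], center_w)
      R_p0 <- frames[[parent]]$R
    }
    loc_c <- pose_invert_apply(frames[[child]], center_w)
    R_rel0 <- t(R_p0) %*% frames[[child]]$R
    # dof axes given in world at calibration; express in parent frame
    dofs <- lapply(dofs, function(d) {
      d$axis <- as.vector(t(R_p0) %*% d$axis)
      d
    })
    joints[[name]] <- list(name = name, parent = parent, child = child,
                           loc_parent = loc_p, loc_child = loc_c,
                           R_rel0 = R_rel0, dofs = dofs)
    joints
  }
  rot_dof <- function(axis, nm) list(type = "rot", axis = axis, name = nm)
  trans_dof <- function(axis, nm) list(type = "trans", axis = axis, name = nm)

  pelv <- frames$pelvis
  joints <- add_joint(joints, "ground_pelvis", "ground", "pelvis", pelv$p, c(
    list(trans_dof(ground_axes[, 1], "pelvis_tx"),
         trans_dof(ground_axes[, 2], "pelvis_ty"),
         trans_dof(ground_axes[, 3], "pelvis_tz")),
    list(rot_dof(pelv$R[, 3], "pelvis_rz"),
         rot_dof(pelv$R[, 1], "pelvis_rx"),
         rot_dof(pelv$R[, 2], "pelvis_ry"))
  ))
  for (side in c("r", "l")) {
    th <- paste0("thigh_", side); sh <- paste0("shank_", side)
    ft <- paste0("foot_", side)
    hipn <- paste0("hip_", side)
    joints <- add_joint(joints, hipn, "pelvis", th, jc[[hipn]], list(
      rot_dof(pelv$R[, 3], paste0(hipn, "_flex")),
      rot_dof(pelv$R[, 1], paste0(hipn, "_add")),
      rot_dof(pelv$R[, 2], paste0(hipn, "_rot"))
    ))
    kneen <- paste0("knee_", side)
    joints <- add_joint(joints, kneen, th, sh, jc[[kneen]],
                        list(rot_dof(jax[[kneen]], paste0(kneen, "_flex"))))
    ankn <- paste0("ankle_", side)
    joints <- add_joint(joints, ankn, sh, ft, jc[[ankn]],
                        list(rot_dof(jax[[ankn]], paste0(ankn, "_flex"))))
  }

  # flatten coordinates
  coord_names <- character(0); coord_joint <- character(0)
  for (j in joints) for (d in j$dofs) {
    coord_names <- c(coord_names, d$name)
    coord_joint <- c(coord_joint, j$name)
  }
  articulated <- coord_joint != "ground_pelvis"

  # per-body chain of joints (root -> body)
  parent_of <- vapply(joints, function(j) j$parent, character(1))
  child_of <- vapply(joints, function(j) j$child, character(1))
  chains <- list()
  for (b in BODY_ORDER) {
    ch <- character(0); cur <- b
    while (cur != "ground") {
      ji <- which(child_of == cur)
      ch <- c(names(joints)[ji], ch)
      cur <- parent_of[ji]
    }
    chains[[b]] <- ch
  }

  model <- structure(list(
    definition = def,
    segments = segments,
    joints = joints,
    chains = chains,
    coord_names = coord_names,
    coord_joint = coord_joint,
    articulated = articulated,
    sigma = def$sigma %||% 61,
    mass = total_mass,
    body_weight = total_mass * GRAVITY
  ), class = "msk_model")
  model$chain_coords <- lapply(stats::setNames(nm = BODY_ORDER), function(b) {
    which(model$coord_joint %in% model$chains[[b]])
  })

  # musculotendon units: body-frame path coordinates + Fmax at neutral pose
  mtus <- list()
  for (m in def$mtus) {
    path <- lapply(m$path, function(pp) {
      list(body = pp$body, role = pp$role,
           pos_body = pose_invert_apply(frames[[pp$body]], pp$pos))
    })
    mt <- list(name = m$name, side = m$side, path = path,
               Vol = m$Vol, l_o_g = m$l_o_g, L_mt_g = m$L_mt_g,
               attachments = m$attachments)
    mtus[[m$name]] <- mt
  }
  model$mtus <- mtus
  q0 <- stats::setNames(rep(0, length(coord_names)), coord_names)
  st <- fk_state(model, q0)
  for (nm in names(mtus)) {
    L <- mtu_length_state(model, st, model$mtus[[nm]])
    model$mtus[[nm]]$L_mt_s <- L * 100  # m -> cm
    model$mtus[[nm]]$Fmax <- estimate_fmax(
      model$mtus[[nm]]$Vol, model$mtus[[nm]]$l_o_g,
      model$mtus[[nm]]$L_mt_g, model$mtus[[nm]]$L_mt_s, model$sigma)
  }
  validate_model(model)
  model
}

#' @export
print.msk_model <- function(x, ...) {
  cat("<msk_model> ", length(x$segments), " segments, ",
      sum(x$articulated), " articulated DOF, ",
      length(x$mtus), " musculotendon units, sigma = ", x$sigma,
      " N/cm^2, mass = ", round(x$mass, 2), " kg\n", sep = "")
  invisible(x)
}

validate_model <- function(model) {
  n_art <- sum(model$articulated)
  if (n_art != 10) {
    stop("mskuq_invalid_model: expected 10 articulated DOF, got ", n_art,
         call. = FALSE)
  }
  for (seg in model$segments) {
    if (seg$mass <= 0) stop("mskuq_invalid_model: non-positive segment mass", call. = FALSE)
    ev <- eigen(seg$inertia, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("mskuq_invalid_model: inertia not positive-definite", call. = FALSE)
    pm <- sort(ev)
    if (pm[3] > pm[1] + pm[2] + 1e-12) {
      stop("mskuq_invalid_model: inertia violates triangle inequality", call. = FALSE)
    }
  }
  for (m in model$mtus) {
    if (length(m$path) < 2) stop("mskuq_invalid_model: MTU path needs >= 2 points", call. = FALSE)
    for (pp in m$path) {
      if (!pp$body %in% names(model$segments)) {
        stop("mskuq_invalid_model: MTU references unknown segment ", pp$body, call. = FALSE)
      }
    }
    if (m$Fmax <= 0) stop("mskuq_invalid_model: non-positive Fmax", call. = FALSE)
  }
  invisible(model)
}

# landmark-derived primitive geometry per segment
build_segment_geometry <- function(seg, frames, jc, lm_world, target_mass,
                                   bvf, dens) {
  base <- sub("_(r|l)$", "", seg)
  side <- if (grepl("_l$", seg)) "L" else "R"
  fr <- frames[[seg]]
  rho_eff <- (bvf * dens[["bone"]] + (1 - bvf) * dens[["soft_tissue"]]) * 1000
  V <- target_mass / rho_eff  # m^3 total
  V_b <- bvf * V; V_s <- (1 - bvf) * V
  if (base == "pelvis") {
    width <- vnorm(lm_world("RASIS") - lm_world("LASIS"))
    depth <- vnorm((lm_world("RASIS") + lm_world("LASIS")) / 2 -
                   (lm_world("RPSIS") + lm_world("LPSIS")) / 2)
    height <- 0.7 * width
    ctr <- pose_invert_apply(fr, fr$p - 0.25 * depth * fr$R[, 1])
    scale3 <- function(Vp) (Vp / (4 / 3 * pi * (depth / 2) * (height / 2) * (width / 2)))^(1 / 3)
    sb <- scale3(V_b); ss <- scale3(V_s)
    parts <- list(
      geometry_part("bone", "ellipsoid",
                    list(a = sb * depth / 2, b = sb * height / 2, c = sb * width / 2), ctr),
      geometry_part("soft_tissue", "ellipsoid",
                    list(a = ss * depth / 2, b = ss * height / 2, c = ss * width / 2), ctr))
  } else {
    ends <- switch(base,
      thigh = list(lm_world(paste0(side, "HC")), jc[[paste0("knee_", tolower(side))]]),
      shank = list(jc[[paste0("knee_", tolower(side))]], jc[[paste0("ankle_", tolower(side))]]),
      foot = list(lm_world(paste0(side, "CA")),
                  (lm_world(paste0(side, "FM")) + lm_world(paste0(side, "VM"))) / 2))
    L <- vnorm(ends[[2]] - ends[[1]])
    ctr <- pose_invert_apply(fr, (ends[[1]] + ends[[2]]) / 2)
    axis_body <- unitv(pose_invert_apply(fr, ends[[2]]) - pose_invert_apply(fr, ends[[1]]))
    # rotation taking local y to the segment long axis
    Rr <- rotation_y_to(axis_body)
    r_b <- sqrt(V_b / (pi * L)); r_s <- sqrt(V_s / (pi * L))
    parts <- list(
      geometry_part("bone", "cylinder", list(radius = r_b, length = L), ctr, Rr),
      geometry_part("soft_tissue", "cylinder", list(radius = r_s, length = L), ctr, Rr))
  }
  list(parts = parts, densities = dens)
}

# rotation mapping e_y to the given unit vector
rotation_y_to <- function(u) {
  ey <- c(0, 1, 0)
  v <- cross3(ey, u); s <- vnorm(v); cth <- sum(ey * u)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(-1, -1, 1)))
  }
  K <- skew3(v / s)
  diag(3) + sin(acos(pmin(pmax(cth, -1), 1))) * K +
    (1 - cth) * (K %*% K)
}

# --- forward kinematics -----------------------------------------------------

# Full kinematic state at configuration q: world pose per body plus, per
# coordinate, the instantaneous world axis and a point on it (for Jacobians).
fk_state <- function(model, q) {
  body_names <- vapply(model$joints, function(j) j$child, character(1))
  poses <- vector("list", length(body_names)); names(poses) <- body_names
  nq <- length(model$coord_names)
  axis_w <- matrix(0, 3, nq)
  point_w <- matrix(0, 3, nq)
  type_tr <- logical(nq)
  ci <- 0L
  for (j in model$joints) {
    if (j$parent == "ground") {
      Rp <- diag(3); pp <- c(0, 0, 0)
    } else {
      Rp <- poses[[j$parent]]$R; pp <- poses[[j$parent]]$p
    }
    tj <- c(0, 0, 0)
    Rj <- diag(3)
    w_base <- pp + as.vector(Rp %*% j$loc_parent)
    for (d in j$dofs) {
      ci <- ci + 1L
      if (d$type == "trans") {
        s <- as.vector(Rp %*% d$axis)
        axis_w[, ci] <- s
        type_tr[ci] <- TRUE
        tj <- tj + d$axis * q[ci]
      } else {
        s <- as.vector(Rp %*% (Rj %*% d$axis))
        axis_w[, ci] <- s
        Rj <- Rj %*% rot_axis_angle(d$axis, q[ci])
      }
    }
    w <- pp + as.vector(Rp %*% (j$loc_parent + tj))
    # rotation dofs act about the (translated) joint point
    nrot <- sum(vapply(j$dofs, function(d) d$type == "rot", logical(1)))
    if (nrot > 0) {
      idx <- (ci - length(j$dofs) + 1L):ci
      for (k in idx) if (!type_tr[k]) point_w[, k] <- w
    }
    Rc <- Rp %*% Rj %*% j$R_rel0
    pc <- w - as.vector(Rc %*% j$loc_child)
    poses[[j$child]] <- list(R = Rc, p = pc)
  }
  list(poses = poses, axis_w = axis_w, point_w = point_w, type_tr = type_tr)
}

# coordinate indices on the chain from ground to body (cached per model)
chain_coords <- function(model, body) {
  cc <- model$chain_coords[[body]]
  if (!is.null(cc)) return(cc)
  which(model$coord_joint %in% model$chains[[body]])
}

# 3 x nq Jacobian of a world point attached to `body`
point_jacobian <- function(model, st, body, pw) {
  nq <- length(model$coord_names)
  J <- matrix(0, 3, nq)
  for (k in chain_coords(model, body)) {
    if (st$type_tr[k]) {
      J[, k] <- st$axis_w[, k]
    } else {
      J[, k] <- cross3(st$axis_w[, k], pw - st$point_w[, k])
    }
  }
  J
}

#' World transforms and point positions at a configuration
#'
#' @param model an `msk_model`.
#' @param q numeric coordinate vector (length = number of model coordinates;
#'   translations in meters, rotations in radians).
#' @return list with `poses` (per-segment `list(R, p)`), `landmarks` (tibble
#'   `segment`, `name`, `x`, `y`, `z`) and `path_points` (tibble `mtu`,
#'   `index`, `role`, `body`, `x`, `y`, `z`).
#' @export
forward_position <- function(model, q) {
  stopifnot(length(q) == length(model$coord_names))
  st <- fk_state(model, q)
  lm_rows <- list()
  for (seg in names(model$segments)) {
    pb <- model$segments[[seg]]$landmarks_body
    if (nrow(pb) == 0) next
    pw <- t(pose_apply(st$poses[[seg]], t(pb)))
    lm_rows[[seg]] <- tibble::tibble(segment = seg, name = rownames(pb),
                                     x = pw[, 1], y = pw[, 2], z = pw[, 3])
  }
  pp_rows <- list()
  for (m in model$mtus) {
    for (i in seq_along(m$path)) {
      pp <- m$path[[i]]
      w <- pose_apply(st$poses[[pp$body]], pp$pos_body)
      pp_rows[[length(pp_rows) + 1L]] <-
        tibble::tibble(mtu = m$name, index = i, role = pp$role,
                       body = pp$body, x = w[1], y = w[2], z = w[3])
    }
  }
  list(poses = st$poses,
       landmarks = dplyr::bind_rows(lm_rows),
       path_points = dplyr::bind_rows(pp_rows))
}

neutral_q <- function(model) {
  stats::setNames(rep(0, length(model$coord_names)), model$coord_names)
}
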