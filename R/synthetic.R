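# Synthetic study data: a template lower-limb model (landmarks, muscle
# paths, attachment areas, architecture parameters) and dynamically
# consistent stance-phase gait trials, so that the full probabilistic
# pipeline runs with no external data. Template coordinates are invented
# plumbing at plausible anatomical scale; no claim is made of matching any
# real subject's anatomy.

#' Default template parameters
#'
#' @param stature subject stature, m
#' @param mass subject body mass, kg
#' @param sigma maximum muscle tension, N/cm^2
#' @param stance_duration stance-phase duration, s
#' @param sample_rate gait sampling rate, Hz
#' @param motion_amplitude scale on the joint-angle program (1 = default
#'   walking stance; 0 = static standing)
#' @param marker_noise_sd_mm marker noise SD, mm (0 = noise-free)
#' @param seed integer seed for any stochastic element (marker noise)
#' @export
template_params <- function(stature = 1.83, mass = 70.5, sigma = 61,
                            stance_duration = 0.6, sample_rate = 50,
                            motion_amplitude = 1, marker_noise_sd_mm = 0,
                            seed = 1) {
  stopifnot(stature > 0, mass > 0, sigma > 0, stance_duration > 0,
            sample_rate > 0, marker_noise_sd_mm >= 0, motion_amplitude >= 0)
  list(stature = stature, mass = mass, sigma = sigma,
       stance_duration = stance_duration, sample_rate = sample_rate,
       motion_amplitude = motion_amplitude,
       marker_noise_sd_mm = marker_noise_sd_mm, seed = seed)
}

# template landmark cloud for a 1.83 m subject (world, standing calibration,
# x anterior, y up, z right); scaled linearly by stature
template_landmarks_183 <- function() {
  L <- rbind(
    c("pelvis", "RASIS",  0.100, 1.020,  0.120),
    c("pelvis", "LASIS",  0.100, 1.020, -0.120),
    c("pelvis", "RPSIS", -0.140, 1.060,  0.050),
    c("pelvis", "LPSIS", -0.140, 1.060, -0.050),
    c("pelvis", "SACRUM", -0.160, 1.080,  0.000),
    c("thigh", "HC",  0.000, 0.950, 0.090),
    c("thigh", "GT", -0.020, 0.930, 0.170),
    c("thigh", "ME",  0.000, 0.530, 0.045),
    c("thigh", "LE",  0.000, 0.530, 0.135),
    c("shank", "MC", -0.010, 0.500, 0.050),
    c("shank", "LC", -0.010, 0.500, 0.130),
    c("shank", "HF", -0.030, 0.490, 0.140),
    c("shank", "TT",  0.035, 0.460, 0.090),
    c("shank", "MM", -0.005, 0.080, 0.055),
    c("shank", "LM", -0.005, 0.080, 0.125),
    c("foot", "CA",  -0.040, 0.030, 0.090),
    c("foot", "FM",   0.160, 0.020, 0.055),
    c("foot", "SM",   0.170, 0.020, 0.090),
    c("foot", "VM",   0.150, 0.020, 0.125),
    c("foot", "PAI", -0.040, 0.015, 0.090),
    c("foot", "PAII", -0.040, 0.002, 0.090)
  )
  tibble::tibble(segment = L[, 1], name = L[, 2],
                 x = as.numeric(L[, 3]), y = as.numeric(L[, 4]),
                 z = as.numeric(L[, 5]))
}

#' Packaged template muscle architecture parameters
#'
#' Plausible muscle volumes (cm^3), generic optimal fiber lengths and
#' generic musculotendon lengths (cm) for the 16 modelled muscles per leg,
#' plus a flag marking deliberately elongated attachment areas.
#'
#' @return tibble with one row per muscle
#' @export
muscle_params_table <- function() {
  path <- system.file("extdata", "muscle_params.csv", package = "mskuq")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# muscle path template (right side, world calibration coordinates).
# roles: origin, pseudo_origin, via, pseudo_insertion, insertion.
# Bodies named without side suffix; mirrored for the left. Architecture
# parameters (volume, generic lengths) come from the packaged CSV.
template_muscles <- function() {
  pars <- muscle_params_table()
  pt <- function(body, role, x, y, z) list(body = body, role = role,
                                           pos = c(x, y, z))
  paths <- list(
    psoas = list(path = list(
      pt("pelvis", "origin", -0.050, 1.060, 0.030),
      pt("pelvis", "pseudo_origin", 0.060, 0.950, 0.060),
      pt("thigh", "insertion", -0.020, 0.890, 0.070))),
    iliacus = list(path = list(
      pt("pelvis", "origin", -0.030, 1.040, 0.060),
      pt("pelvis", "pseudo_origin", 0.055, 0.945, 0.065),
      pt("thigh", "insertion", -0.015, 0.880, 0.075))),
    glmed_a = list(path = list(
      pt("pelvis", "origin", 0.020, 1.050, 0.120),
      pt("thigh", "insertion", -0.010, 0.940, 0.165))),
    glmed_m = list(path = list(
      pt("pelvis", "origin", -0.030, 1.060, 0.130),
      pt("thigh", "insertion", -0.020, 0.935, 0.165))),
    glmed_p = list(path = list(
      pt("pelvis", "origin", -0.070, 1.050, 0.110),
      pt("thigh", "insertion", -0.030, 0.930, 0.160))),
    glmax_a = list(path = list(
      pt("pelvis", "origin", -0.130, 1.040, 0.060),
      pt("thigh", "insertion", -0.040, 0.850, 0.120))),
    tfl = list(path = list(
      pt("pelvis", "origin", 0.090, 1.030, 0.115),
      pt("thigh", "insertion", 0.020, 0.700, 0.150))),
    semimem = list(path = list(
      pt("pelvis", "origin", -0.100, 0.930, 0.050),
      pt("shank", "insertion", -0.035, 0.460, 0.060))),
    recfem = list(path = list(
      pt("pelvis", "origin", 0.080, 0.970, 0.095),
      pt("thigh", "via", 0.045, 0.570, 0.090),
      pt("shank", "insertion", 0.035, 0.460, 0.090))),
    vasmed = list(path = list(
      pt("thigh", "origin", 0.020, 0.750, 0.065),
      pt("thigh", "pseudo_origin", 0.045, 0.560, 0.080),
      pt("shank", "insertion", 0.035, 0.460, 0.085))),
    vaslat = list(path = list(
      pt("thigh", "origin", 0.020, 0.780, 0.120),
      pt("thigh", "pseudo_origin", 0.045, 0.560, 0.100),
      pt("shank", "insertion", 0.035, 0.460, 0.095))),
    vasint = list(path = list(
      pt("thigh", "origin", 0.015, 0.770, 0.090),
      pt("thigh", "pseudo_origin", 0.045, 0.560, 0.090),
      pt("shank", "insertion", 0.035, 0.460, 0.090))),
    gasmed = list(path = list(
      pt("thigh", "origin", -0.035, 0.560, 0.060),
      pt("foot", "insertion", -0.045, 0.035, 0.080))),
    gaslat = list(path = list(
      pt("thigh", "origin", -0.035, 0.560, 0.120),
      pt("foot", "insertion", -0.045, 0.035, 0.100))),
    soleus = list(path = list(
      pt("shank", "origin", -0.040, 0.420, 0.090),
      pt("foot", "insertion", -0.045, 0.035, 0.090))),
    tibant = list(path = list(
      pt("shank", "origin", 0.030, 0.400, 0.080),
      pt("shank", "pseudo_origin", 0.035, 0.105, 0.075),
      pt("foot", "insertion", 0.100, 0.035, 0.060)))
  )
  for (nm in names(paths)) {
    i <- match(nm, pars$muscle)
    stopifnot(!is.na(i))
    paths[[nm]]$Vol <- pars$vol_cm3[i]
    paths[[nm]]$l_o_g <- pars$l_o_g_cm[i]
    paths[[nm]]$L_mt_g <- pars$l_mt_g_cm[i]
    paths[[nm]]$elong <- pars$elongated_attachment[i] == 1
  }
  paths
}

# symmetric attachment-area cloud centered exactly on the point.
# elongated clouds (length/width ratio ~6) exercise the line mode.
attachment_cloud <- function(point, u1, u2, elong = FALSE) {
  if (elong) {
    offs <- rbind(c(0.012, 0.002), c(-0.012, -0.002), c(0.012, -0.002),
                  c(-0.012, 0.002), c(0.006, 0), c(-0.006, 0),
                  c(0, 0.002), c(0, -0.002))
  } else {
    ang <- (0:7) * pi / 4
    offs <- cbind(0.008 * cos(ang), 0.005 * sin(ang))
  }
  pts <- t(apply(offs, 1, function(o) point + o[1] * u1 + o[2] * u2))
  pts
}

mirror_z <- function(p) c(p[1], p[2], -p[3])

#' Generate the template lower-limb model definition and build it
#'
#' Creates a 7-segment, 10-articulated-DOF template: the standard 21
#' anatomical landmarks at anthropometry-scaled positions (left side
#' mirrored), 16 musculotendon units per leg with polyline paths,
#' attachment-area point clouds around every origin and insertion, muscle
#' volumes and generic lengths from a packaged table, and maximum isometric
#' forces initialized at the baseline maximum muscle tension.
#'
#' @param params list from [template_params()]
#' @return an `msk_model`; the buildable definition is in `$definition`
#' @export
generate_template_model <- function(params = template_params()) {
  s <- params$stature / 1.83
  lm0 <- template_landmarks_183()
  lm0$x <- lm0$x * s; lm0$y <- lm0$y * s; lm0$z <- lm0$z * s
  rows <- list()
  for (i in seq_len(nrow(lm0))) {
    seg <- lm0$segment[i]; nm <- lm0$name[i]
    p <- c(lm0$x[i], lm0$y[i], lm0$z[i])
    if (seg == "pelvis") {
      rows[[length(rows) + 1L]] <- c("pelvis", nm, p)
    } else {
      rows[[length(rows) + 1L]] <- c(paste0(seg, "_r"), paste0("R", nm), p)
      rows[[length(rows) + 1L]] <- c(paste0(seg, "_l"), paste0("L", nm), mirror_z(p))
    }
  }
  M <- do.call(rbind, rows)
  landmarks <- tibble::tibble(segment = M[, 1], name = M[, 2],
                              x = as.numeric(M[, 3]), y = as.numeric(M[, 4]),
                              z = as.numeric(M[, 5]))

  mus0 <- template_muscles()
  mtus <- list()
  for (side in c("r", "l")) {
    for (nm in names(mus0)) {
      m <- mus0[[nm]]
      path <- lapply(m$path, function(pp) {
        pos <- pp$pos * s
        if (side == "l") pos <- mirror_z(pos)
        body <- if (pp$body == "pelvis") "pelvis" else paste0(pp$body, "_", side)
        list(body = body, role = pp$role, pos = pos)
      })
      att <- list()
      for (pi in seq_along(path)) {
        if (!path[[pi]]$role %in% c("origin", "insertion")) next
        pidx <- if (path[[pi]]$role == "origin") 1L else length(path)
        p1 <- path[[1]]$pos; p2 <- path[[length(path)]]$pos
        axis <- unitv(p2 - p1)
        lat <- cross3(axis, c(1, 0, 0))
        if (vnorm(lat) < 1e-6) lat <- cross3(axis, c(0, 0, 1))
        lat <- unitv(lat)
        att[[as.character(pi)]] <- attachment_cloud(path[[pi]]$pos, axis, lat,
                                                    elong = m$elong)
      }
      mtus[[length(mtus) + 1L]] <- list(
        name = paste0(nm, "_", side), side = side, path = path,
        Vol = m$Vol, l_o_g = m$l_o_g, L_mt_g = m$L_mt_g,
        attachments = att)
    }
  }

  definition <- list(
    name = "mskuq_template",
    version = "1",
    stature = params$stature,
    mass = params$mass,
    sigma = params$sigma,
    mass_fractions = c(pelvis = 1 - 2 * (0.100 + 0.0465 + 0.0145),
                       thigh = 0.100, shank = 0.0465, foot = 0.0145),
    bone_volume_fraction = 0.15,
    densities = default_densities(),
    landmarks = landmarks,
    mtus = mtus
  )
  build_model(definition)
}

# smooth stance-phase joint angle program (radians), tau in [0, 1]
stance_angle_program <- function(tau) {
  d2r <- pi / 180
  u <- 1.15 * tau - 0.15 * tau^2  # mildly decelerating progression
  c(
    hip_r_flex = (12 - 20 * u) * d2r,
    hip_r_add = (3 * sin(pi * tau)) * d2r,
    hip_r_rot = (2 * sin(2 * pi * tau)) * d2r,
    knee_r_flex = -(5 + 3 * sin(pi * tau) + 4 * u^3) * d2r,
    ankle_r_flex = (-2 + 14 * u) * d2r,
    hip_l_flex = (-6 + 22 * u) * d2r,
    hip_l_add = (-2 * sin(pi * tau)) * d2r,
    hip_l_rot = (-1 * sin(2 * pi * tau)) * d2r,
    knee_l_flex = -(10 + 25 * sin(pi * tau)) * d2r,
    ankle_l_flex = (4 * sin(2 * pi * tau) - 3) * d2r
  )
}

# extract ZXY angles about the fixed axes B = [ax ay az] columns such that
# R = Rot(az,a) Rot(ax,b) Rot(ay,c)
zxy_from_rotation <- function(R, B) {
  S <- t(B) %*% R %*% B
  b <- asin(pmin(pmax(S[3, 2], -1), 1))
  a <- atan2(-S[1, 2], S[2, 2])
  c <- atan2(-S[3, 1], S[3, 3])
  c(a, b, c)
}

#' Generate a dynamically consistent stance-phase gait trial
#'
#' Prescribes smooth joint-angle trajectories over the stance of the right
#' leg, derives the pelvis (root) trajectory so that the right foot stays
#' exactly planted at its calibration pose, synthesizes marker trajectories
#' by forward kinematics (plus optional Gaussian noise), and computes the
#' ground reaction force, centre of pressure and residual plate torque from
#' whole-body Newton-Euler balance using the same finite-difference
#' derivative convention as the analysis pipeline, so that the trial is
#' exactly consistent: the root residual of inverse dynamics is zero to
#' numerical precision at zero marker noise. Ground-truth coordinates and
#' net joint moments are stored alongside the trial.
#'
#' @param model the template `msk_model`
#' @param params list from [template_params()]
#' @return a `gait_trial`: `time`, `markers` (`names`, `xyz` array
#'   frames x markers x 3, m), `grf` (`force`, `cop`, `torque`, `foot`),
#'   `stance_window`, `body_weight` (N), and `ground_truth`
#'   (`q`, `qd`, `qdd`, `moments`, `residual`)
#' @export
generate_gait <- function(model, params = template_params()) {
  n <- round(params$stance_duration * params$sample_rate) + 1L
  time <- seq(0, params$stance_duration, length.out = n)
  tau <- time / params$stance_duration
  nq <- length(model$coord_names)
  Q <- matrix(0, n, nq, dimnames = list(NULL, model$coord_names))
  art_names <- names(stance_angle_program(0))
  # target foot pose: calibration pose of the right foot
  foot0 <- model$segments$foot_r$frame0
  pelv0 <- model$segments$pelvis$frame0
  amp <- params$motion_amplitude %||% 1
  for (t in seq_len(n)) {
    ang <- stance_angle_program(tau[t]) * amp
    q <- neutral_q(model)
    q[art_names] <- ang
    st <- fk_state(model, q)
    # current right-foot pose with pelvis at calibration; solve for the root
    # transform G (world rigid motion) placing the foot at its target:
    # G = T_target T_current^-1, then pelvis pose_new = G pelvis pose_cur.
    fc <- st$poses$foot_r
    Rg <- foot0$R %*% t(fc$R)
    pg <- foot0$p - as.vector(Rg %*% fc$p)
    Rp_new <- Rg %*% st$poses$pelvis$R
    pp_new <- as.vector(Rg %*% st$poses$pelvis$p) + pg
    # root coordinates: R_pelvis = Rj R0, origin translations of calib origin
    Rj <- Rp_new %*% t(pelv0$R)
    eul <- zxy_from_rotation(Rj, pelv0$R)
    q[c("pelvis_rz", "pelvis_rx", "pelvis_ry")] <- eul
    # pelvis origin maps: p_new(origin point) = w where w = p0 + t
    # (rotations act about the translated joint point w = pelvis origin)
    org_new <- pp_new + as.vector(Rp_new %*% pose_invert_apply(pelv0, pelv0$p))
    q[c("pelvis_tx", "pelvis_ty", "pelvis_tz")] <- org_new - pelv0$p
    Q[t, ] <- q
  }
  der <- differentiate(Q, time)
  # whole-body balance -> GRF, CoP, plate torque
  force <- matrix(0, n, 3); cop <- matrix(0, n, 3); torque <- matrix(0, n, 3)
  g_vec <- c(0, -GRAVITY, 0)
  foot_pts <- model$segments$foot_r$landmarks_body
  for (t in seq_len(n)) {
    fd <- fk_dynamics(model, Q[t, ], der$xd[t, ], der$xdd[t, ])
    F <- c(0, 0, 0); Mo <- c(0, 0, 0)
    for (b in names(model$segments)) {
      seg <- model$segments[[b]]
      d <- fd$dyn[[b]]
      R <- fd$st$poses[[b]]$R
      Iw <- R %*% seg$inertia %*% t(R)
      fb <- seg$mass * (d$a_com - g_vec)
      F <- F + fb
      Mo <- Mo + cross3(d$com_w, fb) + as.vector(Iw %*% d$alpha) +
        cross3(d$omega, as.vector(Iw %*% d$omega))
    }
    if (F[2] <= 0) stop("mskuq_invalid_gait: non-positive vertical GRF", call. = FALSE)
    cx <- Mo[3] / F[2]; cz <- -Mo[1] / F[2]
    # clamp CoP into the stance-foot footprint (world bbox of foot landmarks)
    fw <- t(pose_apply(fd$st$poses$foot_r, t(foot_pts)))
    cx <- pmin(pmax(cx, min(fw[, 1])), max(fw[, 1]))
    cz <- pmin(pmax(cz, min(fw[, 3])), max(fw[, 3]))
    cp <- c(cx, 0, cz)
    force[t, ] <- F
    cop[t, ] <- cp
    torque[t, ] <- Mo - cross3(cp, F)
    if (min(fw[, 2]) > 0.08 * params$stature) {
      stop("mskuq_invalid_gait: stance foot is above the ground", call. = FALSE)
    }
  }
  # markers by forward kinematics + optional noise
  lm_names <- all_landmark_names(model)
  xyz <- array(0, dim = c(n, length(lm_names), 3))
  for (t in seq_len(n)) {
    st <- fk_state(model, Q[t, ])
    k <- 0
    for (seg in names(model$segments)) {
      pb <- model$segments[[seg]]$landmarks_body
      pw <- t(pose_apply(st$poses[[seg]], t(pb)))
      xyz[t, k + seq_len(nrow(pb)), ] <- pw
      k <- k + nrow(pb)
    }
  }
  if (params$marker_noise_sd_mm > 0) {
    set.seed(params$seed)
    xyz <- xyz + stats::rnorm(length(xyz), 0, params$marker_noise_sd_mm / 1000)
  }
  external <- lapply(seq_len(n), function(t) {
    e <- list(list(force = force[t, ], point = cop[t, ], torque = torque[t, ]))
    names(e) <- "foot_r"
    e
  })
  idr <- inverse_dynamics(model, Q, der$xd, der$xdd, external)
  structure(list(
    time = time,
    markers = list(names = lm_names, xyz = xyz),
    grf = list(force = force, cop = cop, torque = torque, foot = "foot_r"),
    stance_window = c(1L, n),
    body_weight = model$body_weight,
    ground_truth = list(q = Q, qd = der$xd, qdd = der$xdd,
                        moments = idr$moments, residual = idr$residual)
  ), class = "gait_trial")
}

#' Closed-form toy fixtures for solver validation
#'
#' Small models with known analytic solutions: a gravity pendulum, a planar
#' double pendulum, and one-joint one/two-muscle systems used across the
#' test suite.
#'
#' @return named list of fixture constructors / parameter sets
#' @export
toy_fixtures <- function() {
  list(
    pendulum = function(m = 2, d = 0.4, I = 0.02) {
      toy_chain_model(list(list(mass = m, com_d = d, inertia = I, length = 0.8)))
    },
    double_pendulum = function(m1 = 2, m2 = 1.2, l1 = 0.5, lc1 = 0.3,
                               lc2 = 0.25, I1 = 0.03, I2 = 0.015) {
      toy_chain_model(list(
        list(mass = m1, com_d = lc1, inertia = I1, length = l1),
        list(mass = m2, com_d = lc2, inertia = I2, length = 0.5)))
    },
    one_muscle = list(r = 0.05, Fmax = 1000),
    two_muscle = list(r = c(0.04, 0.06), Fmax = c(1000, 1500))
  )
}

# serial chain of hinge links (z-axis hinges, links hanging along -y),
# wrapped in the minimal msk_model interface used by the dynamics code
toy_chain_model <- function(links) {
  segments <- list(); joints <- list(); chains <- list()
  coord_names <- character(0); coord_joint <- character(0)
  prev <- "ground"; y0 <- 0
  for (i in seq_along(links)) {
    lk <- links[[i]]
    nm <- paste0("link", i)
    segments[[nm]] <- list(
      name = nm, mass = lk$mass, com = c(0, -lk$com_d, 0),
      inertia = diag(c(lk$inertia, 1e-6, lk$inertia)),
      frame0 = list(R = diag(3), p = c(0, y0, 0)),
      landmarks_body = matrix(numeric(0), 0, 3))
    jn <- paste0("hinge", i)
    joints[[jn]] <- list(
      name = jn, parent = prev, child = nm,
      loc_parent = if (prev == "ground") c(0, y0, 0) else c(0, -links[[i - 1]]$length, 0),
      loc_child = c(0, 0, 0), R_rel0 = diag(3),
      dofs = list(list(type = "rot", axis = c(0, 0, 1), name = paste0("q", i))))
    coord_names <- c(coord_names, paste0("q", i))
    coord_joint <- c(coord_joint, jn)
    chains[[nm]] <- names(joints)
    prev <- nm
    y0 <- y0 - lk$length
  }
  structure(list(
    definition = NULL, segments = segments, joints = joints, chains = chains,
    coord_names = coord_names, coord_joint = coord_joint,
    articulated = rep(TRUE, length(coord_names)),
    sigma = 61, mass = sum(vapply(links, function(l) l$mass, numeric(1))),
    body_weight = sum(vapply(links, function(l) l$mass, numeric(1))) * GRAVITY,
    mtus = list()
  ), class = "msk_model")
}
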