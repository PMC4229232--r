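# Segment inertial properties from two-density primitive geometry.

default_densities <- function() c(bone = 1.42, soft_tissue = 1.03)  # g/cm^3

#' Define a geometric primitive for segment inertia
#'
#' @param role `"bone"` or `"soft_tissue"`; selects the density.
#' @param primitive `"cylinder"` (solid, axis along local y; dims `radius`,
#'   `length`), `"ellipsoid"` (dims semi-axes `a`, `b`, `c` along local
#'   x/y/z), or `"point_cloud"` (dims `points` n x 3 matrix and total
#'   `volume` in m^3, treated as equal point masses).
#' @param dims named list of dimensions in meters (volume in m^3).
#' @param center primitive center in the body frame (m).
#' @param R 3x3 orientation of the primitive in the body frame.
#' @export
geometry_part <- function(role, primitive, dims, center = c(0, 0, 0), R = diag(3)) {
  stopifnot(role %in% c("bone", "soft_tissue"),
            primitive %in% c("cylinder", "ellipsoid", "point_cloud"))
  list(role = role, primitive = primitive, dims = dims,
       center = center, R = R)
}

primitive_volume <- function(part) {
  d <- part$dims
  switch(part$primitive,
    cylinder = pi * d$radius^2 * d$length,
    ellipsoid = 4 / 3 * pi * d$a * d$b * d$c,
    point_cloud = d$volume
  )
}

# inertia of the primitive about its own center, in its local axes, per unit mass
primitive_unit_inertia <- function(part) {
  d <- part$dims
  switch(part$primitive,
    cylinder = {
      r <- d$radius; L <- d$length
      diag(c((3 * r^2 + L^2) / 12, r^2 / 2, (3 * r^2 + L^2) / 12))
    },
    ellipsoid = diag(c(d$b^2 + d$c^2, d$a^2 + d$c^2, d$a^2 + d$b^2)) / 5,
    point_cloud = {
      pts <- d$points
      ctr <- colMeans(pts)
      pc <- sweep(pts, 2, ctr)
      J <- matrix(0, 3, 3)
      for (i in seq_len(nrow(pc))) {
        x <- pc[i, ]
        J <- J + (sum(x * x) * diag(3) - outer(x, x))
      }
      J / nrow(pc)
    }
  )
}

#' Mass, center of mass and inertia tensor of a two-density segment
#'
#' Composes the inertial properties of a segment from its bone and
#' soft-tissue primitives, each with a uniform density (defaults
#' 1.42 and 1.03 g/cm^3). Inertia is composed about the combined center of
#' mass via the parallel-axis theorem.
#'
#' @param geometry list with `parts` (list of [geometry_part()]) and
#'   optionally `densities` (named, g/cm^3).
#' @return list with `mass` (kg), `com` (3-vector, body frame, m) and
#'   `inertia` (3x3, kg m^2, about the com in body axes).
#' @export
compute_inertial_properties <- function(geometry) {
  dens <- geometry$densities %||% default_densities()
  if (any(dens <= 0)) stop("mskuq_invalid_density: densities must be > 0", call. = FALSE)
  parts <- geometry$parts
  masses <- numeric(length(parts))
  coms <- matrix(0, length(parts), 3)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    dim_ok <- switch(p$primitive,
      cylinder = p$dims$radius > 0 && p$dims$length > 0,
      ellipsoid = p$dims$a > 0 && p$dims$b > 0 && p$dims$c > 0,
      point_cloud = p$dims$volume > 0 && nrow(p$dims$points) >= 1)
    if (!isTRUE(dim_ok)) {
      stop("mskuq_invalid_dimension: non-positive primitive dimension", call. = FALSE)
    }
    rho <- dens[[p$role]] * 1000  # g/cm^3 -> kg/m^3
    masses[i] <- rho * primitive_volume(p)
    ctr <- if (p$primitive == "point_cloud") {
      as.vector(p$center + p$R %*% colMeans(p$dims$points))
    } else p$center
    coms[i, ] <- ctr
  }
  mass <- sum(masses)
  com <- colSums(coms * masses) / mass
  inertia <- matrix(0, 3, 3)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    I_loc <- masses[i] * primitive_unit_inertia(p)
    I_body <- p$R %*% I_loc %*% t(p$R)
    d <- coms[i, ] - com
    inertia <- inertia + I_body +
      masses[i] * (sum(d * d) * diag(3) - outer(d, d))
  }
  list(mass = mass, com = com, inertia = inertia)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
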