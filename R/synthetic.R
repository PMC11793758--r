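#' Parameters of the synthetic arch appliance
#'
#' The synthetic specimen is a geometric analog of a maxillary stabilisation
#' splint: a horseshoe (U-shaped) band swept along a parabolic dental arch,
#' with a flat occlusal top, vertical buccal (outer) and palatal (inner)
#' walls, a flat underside, and capped posterior ends.  It is not an
#' anatomical model; it exists so that known deformations can be applied and
#' recovered.
#'
#' @param span total left-right width of the arch (mm, outer wall to outer
#'   wall at the posterior ends).
#' @param depth anterior-posterior depth of the arch (mm).
#' @param band_width width of the band cross-section (mm); the analog of the
#'   ~2 mm palatal wall plus occlusal coverage.
#' @param occlusal_height height of the band (mm).
#' @param resolution target edge length (mm); must be at most
#'   `band_width / 4`.
#' @param seed integer seed (the construction is deterministic; the seed is
#'   carried for provenance and future stochastic variants).
#' @return object of class `arch_params`.
#' @export
arch_params <- function(span = 50, depth = 40, band_width = 8,
                        occlusal_height = 3, resolution = 0.5, seed = 1L) {
  p <- list(span = span, depth = depth, band_width = band_width,
            occlusal_height = occlusal_height, resolution = resolution,
            seed = as.integer(seed))
  if (any(unlist(p[1:5]) <= 0)) stop("all arch parameters must be positive")
  if (resolution > band_width / 4)
    stop("resolution must be at most band_width / 4")
  structure(p, class = "arch_params")
}

# arc-length reparameterisation of the parabolic centerline
# x(t) = a t, y(t) = dc t^2, t in [-1, 1]
arch_centerline <- function(a, dc, n_samples) {
  tt <- seq(-1, 1, length.out = 2048)
  speed <- sqrt(a^2 + (2 * dc * tt)^2)
  s <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(tt)))
  target <- seq(0, s[length(s)], length.out = n_samples)
  stats::approx(s, tt, xout = target, ties = "ordered")$y
}

#' Generate the synthetic arch appliance mesh
#'
#' Coordinate convention: z is occlusal (up), the anterior of the arch faces
#' -y, the posterior arm ends are at maximum y, and the mesh is centred at
#' the origin in x and y (z runs from `-occlusal_height/2` to
#' `+occlusal_height/2`).  Per-vertex generator attributes (`region`, lateral
#' coordinate `u`, profile height `z0`, arch parameter `t`, inward horizontal
#' direction `indir_*`) are attached for use by [apply_deformation()].
#'
#' @param params an [arch_params()] object.
#' @return an `oca_mesh` with generator attributes.
#' @export
generate_arch_appliance <- function(params) {
  stopifnot(inherits(params, "arch_params"))
  w <- params$band_width
  h <- params$occlusal_height
  res <- params$resolution
  a <- (params$span - w) / 2
  dc <- params$depth - w / 2
  if (a <= 0 || dc <= 0) stop("infeasible arch: span/depth too small for band width")

  # closed cross-section loop in (u, z): counter-clockwise so that the swept
  # surface is outward-oriented.  u > 0 is buccal (outer), u < 0 palatal.
  seg <- function(p0, p1) {
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(1L, ceiling(len / res))
    s <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    cbind(p0[1] + s * (p1[1] - p0[1]), p0[2] + s * (p1[2] - p0[2]))
  }
  loop <- rbind(seg(c(-w / 2, 0), c(w / 2, 0)),   # bottom (palatal -> buccal)
                seg(c(w / 2, 0), c(w / 2, h)),    # outer (buccal) wall
                seg(c(w / 2, h), c(-w / 2, h)),   # occlusal top
                seg(c(-w / 2, h), c(-w / 2, 0)))  # inner (palatal) wall
  ns <- nrow(loop)
  region_of <- function(u, z0) {
    ifelse(z0 <= 1e-12, "bottom",
           ifelse(z0 >= h - 1e-12, "top",
                  ifelse(u > 0, "outer", "inner")))
  }
  loop_region <- region_of(loop[, 1], loop[, 2])

  # arch sampling: uniform arc length along the centerline
  speed_max <- sqrt(a^2 + (2 * dc)^2)
  arc_len <- {
    tt <- seq(-1, 1, length.out = 2048)
    sp <- sqrt(a^2 + (2 * dc * tt)^2)
    sum((sp[-1] + sp[-length(sp)]) / 2 * diff(tt))
  }
  nt <- max(2L, ceiling(arc_len / res))
  tvals <- arch_centerline(a, dc, nt + 1L)

  # arc length along the centerline at each sampled t (mm, from t = -1)
  svals <- {
    tt <- seq(-1, 1, length.out = 2048)
    sp <- sqrt(a^2 + (2 * dc * tt)^2)
    cums <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tt)))
    stats::approx(tt, cums, xout = tvals, ties = "ordered")$y
  }

  nv_band <- (nt + 1L) * ns
  V <- matrix(0, nv_band + 2L, 3)
  att_u <- numeric(nv_band + 2L)
  att_z0 <- numeric(nv_band + 2L)
  att_t <- numeric(nv_band + 2L)
  att_s <- numeric(nv_band + 2L)
  att_region <- character(nv_band + 2L)
  att_inx <- numeric(nv_band + 2L)
  att_iny <- numeric(nv_band + 2L)

  for (i in seq_len(nt + 1L)) {
    t <- tvals[i]
    cx <- a * t
    cy <- dc * t^2
    tang <- c(a, 2 * dc * t)
    tang <- tang / sqrt(sum(tang^2))
    lat <- c(tang[2], -tang[1])  # outward horizontal normal
    rows <- ((i - 1L) * ns + 1L):(i * ns)
    V[rows, 1] <- cx + loop[, 1] * lat[1]
    V[rows, 2] <- cy + loop[, 1] * lat[2]
    V[rows, 3] <- loop[, 2]
    att_u[rows] <- loop[, 1]
    att_z0[rows] <- loop[, 2]
    att_t[rows] <- t
    att_s[rows] <- svals[i]
    att_region[rows] <- loop_region
    att_inx[rows] <- -lat[1]
    att_iny[rows] <- -lat[2]
  }
  # cap centroids
  for (side in 1:2) {
    i <- if (side == 1L) 1L else nt + 1L
    rows <- ((i - 1L) * ns + 1L):(i * ns)
    cid <- nv_band + side
    V[cid, ] <- colMeans(V[rows, , drop = FALSE])
    att_u[cid] <- 0
    att_z0[cid] <- h / 2
    att_t[cid] <- tvals[i]
    att_s[cid] <- svals[i]
    att_region[cid] <- "cap"
    att_inx[cid] <- att_inx[rows[1]]
    att_iny[cid] <- att_iny[rows[1]]
  }

  # band faces: quad (i,j)-(i+1,j)-(i+1,j+1)-(i,j+1), j modular over the loop
  vid <- function(i, j) (i - 1L) * ns + ((j - 1L) %% ns) + 1L
  i <- rep(seq_len(nt), each = ns)
  j <- rep(seq_len(ns), times = nt)
  f1 <- cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L))
  f2 <- cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  # cap fans (outward: -tangent at t = -1, +tangent at t = +1)
  jj <- seq_len(ns)
  cap1 <- cbind(nv_band + 1L, vid(1L, jj), vid(1L, jj + 1L))
  cap2 <- cbind(nv_band + 2L, vid(nt + 1L, jj + 1L), vid(nt + 1L, jj))
  F <- rbind(f1, f2, cap1, cap2)

  # centre in x and y; centre z
  V[, 1] <- V[, 1] - (max(V[, 1]) + min(V[, 1])) / 2
  V[, 2] <- V[, 2] - (max(V[, 2]) + min(V[, 2])) / 2
  V[, 3] <- V[, 3] - h / 2

  triangle_mesh(V, F,
                attributes = list(region = att_region, u = att_u,
                                  z0 = att_z0, t = att_t, s = att_s,
                                  indir_x = att_inx, indir_y = att_iny))
}

#' Deformation scenario
#'
#' Parametric description of the storage-induced deformation pattern applied
#' to the synthetic appliance: the posterior margins shrink anteriorly, the
#' palatal side of the molar region lifts occlusally, and the buccal side
#' retracts inward.  Magnitudes are peak displacements in mm; the spatial
#' weight fields are cosine-tapered with the given smoothness length and
#' normalised so the stated magnitude is attained exactly at the field
#' maximum.
#'
#' @param posterior_shrink peak anterior pull of the posterior margins (mm).
#' @param palatal_lift peak occlusal (+z) lift of the inner/occlusal molar
#'   region (mm).
#' @param buccal_retraction peak inward displacement of the outer wall in the
#'   molar region (mm).
#' @param smoothness spatial taper length (mm); default 10.
#' @param seed integer seed carried for provenance.
#' @return object of class `deformation_scenario`.
#' @export
deformation_scenario <- function(posterior_shrink = 0, palatal_lift = 0,
                                 buccal_retraction = 0, smoothness = 10,
                                 seed = 1L) {
  if (posterior_shrink < 0 || palatal_lift < 0 || buccal_retraction < 0)
    stop("deformation magnitudes must be non-negative")
  if (smoothness <= 0) stop("smoothness length must be positive")
  structure(list(posterior_shrink = posterior_shrink,
                 palatal_lift = palatal_lift,
                 buccal_retraction = buccal_retraction,
                 smoothness = smoothness, seed = as.integer(seed)),
            class = "deformation_scenario")
}

# smooth 0..1 ramp: 0 at g<=0, 1 at g>=1, cosine in between
taper01 <- function(g) {
  g <- pmin(pmax(g, 0), 1)
  0.5 - 0.5 * cos(pi * g)
}

# deformation weight fields; each is normalised to max 1 over the mesh
deformation_weights <- function(mesh, smoothness) {
  at <- mesh$attributes
  if (is.null(at) || is.null(at$u) || is.null(at$z0) || is.null(at$indir_x))
    stop("apply_deformation needs a mesh produced by generate_arch_appliance (generator attributes missing)")
  v <- mesh$vertices
  w_band <- diff(range(at$u))
  h <- max(at$z0)
  L <- smoothness

  # posterior: ramp up over the last L mm of y toward the posterior ends
  ymax <- max(v[, 2])
  w_post <- taper01((v[, 2] - (ymax - L)) / L)

  # longitudinal molar envelope for lift/retraction: cosine peaks centred on
  # the molar regions of both arms (arch parameter t = +/- 0.7)
  s_mol <- stats::approx(at$t, at$s, xout = c(-0.7, 0.7), ties = "ordered")$y
  e_mol <- pmax(1 - taper01(abs(at$s - s_mol[1]) / L),
                1 - taper01(abs(at$s - s_mol[2]) / L))

  # palatal lift: profile distance from the peak point on the inner half of
  # the occlusal top (u = -w/4, z = top)
  d_lift <- abs(at$u + w_band / 4) + (h - at$z0)
  w_lift <- (1 - taper01(d_lift / L)) * e_mol

  # buccal retraction: profile distance from outer wall mid-height
  d_buc <- (w_band / 2 - at$u) + abs(at$z0 - h / 2)
  w_buc <- (1 - taper01(d_buc / L)) * e_mol

  norm1 <- function(x) if (max(x) > 0) x / max(x) else x
  list(posterior = norm1(w_post), lift = norm1(w_lift), buccal = norm1(w_buc))
}

#' Apply a parametric deformation to a synthetic appliance
#'
#' Displaces vertices by a smooth field combining the three components of
#' the scenario (see [deformation_scenario()]); mesh topology is unchanged.
#' The mesh must carry the generator attributes of
#' [generate_arch_appliance()].  A zero scenario is an exact identity.
#'
#' @param mesh generator-produced `oca_mesh`.
#' @param scenario a [deformation_scenario()].
#' @return deformed `oca_mesh`.
#' @export
apply_deformation <- function(mesh, scenario) {
  stopifnot(inherits(scenario, "deformation_scenario"))
  w <- deformation_weights(mesh, scenario$smoothness)
  at <- mesh$attributes
  disp <- matrix(0, nrow(mesh$vertices), 3)
  disp[, 2] <- disp[, 2] - scenario$posterior_shrink * w$posterior
  disp[, 3] <- disp[, 3] + scenario$palatal_lift * w$lift
  disp[, 1] <- disp[, 1] + scenario$buccal_retraction * w$buccal * at$indir_x
  disp[, 2] <- disp[, 2] + scenario$buccal_retraction * w$buccal * at$indir_y
  out <- mesh
  out$vertices <- mesh$vertices + disp
  # guard against triangle inversion under extreme magnitudes
  n0 <- face_geometry(mesh)$weighted
  n1 <- face_geometry(out)$weighted
  flipped <- which(rowSums(n0 * n1) <= 0 & rowSums(n0^2) > 0)
  if (length(flipped) > 0L) {
    stop("deformation inverts ", length(flipped), " triangles (faces ",
         paste(utils::head(flipped, 10), collapse = ", "), " ...)")
  }
  out
}

#' Add scanner noise along vertex normals
#'
#' Displaces each vertex along its unit normal by i.i.d. zero-mean Gaussian
#' offsets with the given standard deviation, mimicking the line-of-sight
#' error of an optical surface scanner.  Deterministic per seed.
#'
#' @param mesh an `oca_mesh`.
#' @param sigma_mm noise standard deviation (mm); 0 is an exact identity.
#' @param seed integer seed.
#' @return noisy `oca_mesh`.
#' @export
apply_scan_noise <- function(mesh, sigma_mm, seed) {
  if (sigma_mm < 0) stop("sigma must be non-negative")
  if (sigma_mm == 0) return(mesh)
  nrm <- if (!is.null(mesh$normals)) mesh$normals else compute_vertex_normals(mesh)
  off <- with_seed(seed, stats::rnorm(nrow(mesh$vertices), 0, sigma_mm))
  out <- mesh
  out$vertices <- mesh$vertices + nrm * off
  out
}

#' Synthetic scan of a calibration sphere
#'
#' Points are drawn area-uniformly on the sphere and perturbed radially by
#' Gaussian noise, emulating a scanned acrylic calibration sphere.
#'
#' @param radius_mm true sphere radius (mm); the study's spheres are
#'   2.5/8 inch = 7.940 mm.
#' @param center numeric length-3 centre (mm).
#' @param n_points number of points (at least 4).
#' @param sigma_mm radial noise SD (mm).
#' @param seed integer seed.
#' @return object of class `sphere_point_cloud` with fields `points`,
#'   `radius` (nominal true radius) and `center`.
#' @export
generate_sphere_scan <- function(radius_mm = 7.940, center = c(0, 0, 0),
                                 n_points = 5000L, sigma_mm = 0, seed = 1L) {
  if (n_points < 4L) stop("need at least 4 points")
  if (radius_mm <= 0) stop("radius must be positive")
  pts <- with_seed(seed, {
    z <- stats::runif(n_points, -1, 1)
    th <- stats::runif(n_points, 0, 2 * pi)
    r <- radius_mm + if (sigma_mm > 0) stats::rnorm(n_points, 0, sigma_mm) else 0
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(r * s * cos(th), r * s * sin(th), r * z)
  })
  pts <- sweep(pts, 2, center, "+")
  structure(list(points = pts, radius = radius_mm, center = center),
            class = "sphere_point_cloud")
}
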