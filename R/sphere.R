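#' Least-squares sphere fit
#'
#' Algebraic linear least squares on |p|^2 = 2 c.p + (r^2 - |c|^2) for the
#' centre and radius, refined by up to `refine_iter` Gauss-Newton steps on
#' the geometric objective sum(|p - c| - r)^2.
#'
#' @param points numeric matrix n x 3 (mm), n >= 4, non-coplanar.
#' @param refine_iter maximum Gauss-Newton refinement steps (default 20).
#' @return object of class `sphere_fit`: list with `center`, `radius` (mm),
#'   `rms_residual` (RMS radial residual, mm) and `n`.
#' @export
fit_sphere_least_squares <- function(points, refine_iter = 20L) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points to fit a sphere")
  A <- cbind(2 * points, 1)
  bb <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate point configuration (coplanar or coincident points)")
  sol <- qr.coef(qrA, bb)
  ctr <- sol[1:3]
  r <- sqrt(max(sol[4] + sum(ctr^2), 0))
  # Gauss-Newton refinement of (center, radius)
  for (it in seq_len(refine_iter)) {
    dvec <- sweep(points, 2, ctr)
    dist <- sqrt(rowSums(dvec^2))
    if (any(dist == 0)) break
    res <- dist - r
    J <- cbind(-dvec / dist, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    ctr <- ctr + step[1:3]
    r <- r + step[4]
    if (max(abs(step)) < 1e-14) break
  }
  dist <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  structure(list(center = as.numeric(ctr), radius = r,
                 rms_residual = sqrt(mean((dist - r)^2)),
                 n = nrow(points)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> r = %.6f mm, center (%.4f, %.4f, %.4f), RMS residual %.2e mm (n = %d)\n",
              x$radius, x$center[1], x$center[2], x$center[3],
              x$rms_residual, x$n))
  invisible(x)
}

#' Scanner accuracy protocol by repeated sphere fitting
#'
#' Mirrors the calibration procedure of a dental model scanner: from one
#' scanned calibration sphere, draw `n_points` points at random (without
#' replacement, a fresh draw each iteration), fit the sphere by least
#' squares, and repeat `n_iterations` times.  Trueness is the signed
#' difference between the mean fitted radius and the true radius; precision
#' is the standard deviation of the fitted radii.
#'
#' @param cloud a `sphere_point_cloud` (see [generate_sphere_scan()]), or a
#'   list with `points` (n x 3) and `radius` (true radius, mm).
#' @param n_points points per subsample (default 100, at least 4).
#' @param n_iterations number of repeated fits (default 1000).
#' @param seed integer seed.
#' @param replace sample with replacement instead (default FALSE).
#' @return object of class `accuracy_report`: list with `radii` (mm),
#'   `mean_radius`, `trueness`, `precision` (mm), `n_points`,
#'   `n_iterations`, `seed`.
#' @export
accuracy_protocol <- function(cloud, n_points = 100L, n_iterations = 1000L,
                              seed = 1L, replace = FALSE) {
  pts <- cloud$points
  if (n_points < 4L) stop("n_points must be at least 4")
  if (nrow(pts) < n_points) stop("cloud has fewer than n_points points")
  radii <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      idx <- sample.int(nrow(pts), n_points, replace = replace)
      fit_sphere_least_squares(pts[idx, , drop = FALSE])$radius
    }, 0)
  })
  structure(list(radii = radii,
                 mean_radius = mean(radii),
                 trueness = mean(radii) - cloud$radius,
                 precision = stats::sd(radii),
                 n_points = as.integer(n_points),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> trueness %.4f mm, precision %.4f mm (%d x %d points)\n",
              x$trueness, x$precision, x$n_iterations, x$n_points))
  invisible(x)
}

#' Derive the analysis cutoff from an accuracy report
#'
#' The deviation cutoff is |trueness| + precision, rounded up to the nearest
#' 0.010 mm (with a minimum of one grid step).  This rule is an interpretive
#' reconstruction of the published calibration step, where a trueness of
#' 10.7 um and a precision of 27.9 um led to a +/- 40 um cutoff: it
#' reproduces 0.0107 + 0.0279 = 0.0386 -> 0.040 mm.
#'
#' @param report an `accuracy_report`, or any list with `trueness` and
#'   `precision` (mm).
#' @return cutoff in mm.
#' @export
derive_cutoff <- function(report) {
  x <- abs(report$trueness) + report$precision
  k <- ceiling(round(x / 0.010, 9))
  max(k, 1) * 0.010
}

#' Write an accuracy report to JSON
#' @param report an `accuracy_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an accuracy report from JSON
#' @param path JSON written by [write_accuracy_report()].
#' @return an `accuracy_report`.
#' @export
read_accuracy_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "accuracy_report")
}
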