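#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix, orthonormal with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not a proper rotation (orthonormal, det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_angle_deg <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c))) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @return a `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), as.numeric(-t(tr$rotation) %*% tr$translation))
}

transform_points <- function(points, tr) {
  sweep(points %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex by `R v + t`; faces (and carried attributes) unchanged.
#' Stored normals are rotated.
#'
#' @param mesh an `oca_mesh`.
#' @param tr a `rigid_transform`.
#' @return transformed `oca_mesh`.
#' @export
apply_transform <- function(mesh, tr) {
  out <- mesh
  out$vertices <- transform_points(mesh$vertices, tr)
  if (!is.null(mesh$normals)) out$normals <- mesh$normals %*% t(tr$rotation)
  out
}

#' Nearest point on a mesh surface
#'
#' For each query point, the globally closest point on the closed triangles
#' of the mesh (vertex, edge or interior), found through a uniform-grid
#' spatial index.
#'
#' @param mesh reference `oca_mesh`.
#' @param query numeric matrix n x 3 of query points (mm).
#' @return list with `point` (n x 3 closest points), `face` (1-based face
#'   ids), `distance` (mm) and `bary` (n x 3 barycentric coordinates of the
#'   closest point within its face).
#' @export
nearest_point_on_surface <- function(mesh, query) {
  if (nrow(mesh$faces) == 0L) stop("reference mesh has no faces")
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  storage.mode(query) <- "double"
  f0 <- mesh$faces - 1L  # C++ takes 0-based faces
  cpp_nearest_points(mesh$vertices, f0, query)
}

# Closed-form least-squares rigid motion taking P onto Q (Kabsch/Umeyama,
# SVD of the cross-covariance with a reflection guard).
solve_rigid_motion <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, qc - as.numeric(R %*% pc))
}

#' Best-fit rigid alignment (iterative closest point)
#'
#' Aligns `test` onto `reference` by repeatedly matching each (sampled) test
#' vertex to its nearest point on the reference surface and solving the
#' closed-form least-squares rigid motion, until the RMS nearest-point
#' distance stabilises.  Correspondences are point-to-point against the
#' closed reference triangles.  Initialisation is the identity: pairs are
#' assumed to share a frame (two scans of the same specimen).
#'
#' @param test `oca_mesh` to be moved (the later time point).
#' @param reference fixed `oca_mesh` (the earlier time point).
#' @param max_iter maximum iterations (default 200).
#' @param rms_tol convergence tolerance on the change in RMS distance (mm,
#'   default 1e-6); an RMS at or below the tolerance also converges.
#' @param sample_size use at most this many test vertices (default 50000);
#'   sampled once, without replacement.
#' @param seed integer seed, required when the mesh is larger than
#'   `sample_size`.
#' @param trim optional fraction in \[0, 1): drop this upper fraction of
#'   correspondence distances each iteration (off by default; specimens are
#'   assumed to overlap fully).
#' @param init `"identity"` (default; scan pairs share a frame) or
#'   `"centroid"` (pre-align vertex centroids, for rigidly displaced inputs).
#' @return list with `transform` (a `rigid_transform`) and `report` (final
#'   RMS, per-iteration RMS history, iterations, converged flag, sample size).
#' @export
best_fit_align <- function(test, reference, max_iter = 200L, rms_tol = 1e-6,
                           sample_size = 50000L, seed = NULL, trim = 0,
                           init = c("identity", "centroid")) {
  init <- match.arg(init)
  if (!all(is.finite(test$vertices)) || !all(is.finite(reference$vertices)))
    stop("non-finite geometry")
  if (nrow(reference$faces) == 0L || nrow(test$vertices) == 0L)
    stop("empty mesh passed to best_fit_align")
  nv <- nrow(test$vertices)
  if (nv > sample_size) {
    if (is.null(seed)) stop("seed is required when sampling test vertices")
    idx <- with_seed(seed, sample.int(nv, sample_size))
  } else {
    idx <- seq_len(nv)
  }
  P0 <- test$vertices[idx, , drop = FALSE]
  tr <- if (init == "centroid") {
    rigid_transform(diag(3),
                    colMeans(reference$vertices) - colMeans(test$vertices))
  } else {
    rigid_transform()
  }
  rms_history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  prev_rms <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- transform_points(P0, tr)
    nn <- nearest_point_on_surface(reference, P)
    keep <- seq_len(nrow(P))
    if (trim > 0) {
      keep <- which(nn$distance <= stats::quantile(nn$distance, 1 - trim))
    }
    rms <- sqrt(mean(nn$distance[keep]^2))
    rms_history <- c(rms_history, rms)
    if (rms <= rms_tol || abs(prev_rms - rms) < rms_tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    step <- solve_rigid_motion(P[keep, , drop = FALSE],
                               nn$point[keep, , drop = FALSE])
    tr <- compose_transform(step, tr)
  }
  list(transform = tr,
       report = list(rms = rms_history[length(rms_history)],
                     rms_history = rms_history,
                     iterations = iter,
                     converged = converged,
                     sample_size = length(idx)))
}

# evaluate a deterministic expression under a local RNG state
with_seed <- function(seed, expr) {
  # force the seed before snapshotting: it may itself consume the caller RNG
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialise a rigid transform to JSON
#' @param tr a `rigid_transform`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_transform_json <- function(tr, path) {
  jsonlite::write_json(list(rotation = tr$rotation,
                            translation = tr$translation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON file written by [write_transform_json()].
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(unlist(x$rotation), 3, 3), unlist(x$translation))
}
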