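#' Signed surface deviation field
#'
#' For every vertex of the (already aligned) test mesh, the distance to the
#' nearest point on the reference surface, signed by the reference normal at
#' the contact point: positive where the test surface lies outside/above the
#' reference, negative below.  The normal is interpolated barycentrically
#' from the reference vertex normals and falls back to the face normal where
#' the interpolated normal degenerates.
#'
#' @param test_aligned test `oca_mesh`, already aligned onto the reference
#'   (see [best_fit_align()]).
#' @param reference reference `oca_mesh`.
#' @return object of class `deviation_field`: list with `deviation`
#'   (numeric, mm, one per test vertex), `mesh` (the test mesh) and `nearest`
#'   (the raw nearest-point query result).
#' @export
signed_deviation_field <- function(test_aligned, reference) {
  nn <- nearest_point_on_surface(reference, test_aligned$vertices)
  vn <- compute_vertex_normals(reference)
  f <- reference$faces[nn$face, , drop = FALSE]
  n_interp <- nn$bary[, 1] * vn[f[, 1], , drop = FALSE] +
    nn$bary[, 2] * vn[f[, 2], , drop = FALSE] +
    nn$bary[, 3] * vn[f[, 3], , drop = FALSE]
  len <- sqrt(rowSums(n_interp^2))
  degen <- len < 1e-9
  if (any(degen)) {
    fn <- face_geometry(reference)$normal
    n_interp[degen, ] <- fn[nn$face[degen], , drop = FALSE]
    len[degen] <- 1
  }
  n_interp <- n_interp / len
  dvec <- test_aligned$vertices - nn$point
  sgn <- sign(rowSums(dvec * n_interp))
  structure(list(deviation = sgn * nn$distance,
                 mesh = test_aligned,
                 nearest = nn),
            class = "deviation_field")
}

#' @export
print.deviation_field <- function(x, ...) {
  cat(sprintf("<deviation_field> %d vertices, range [%.4f, %.4f] mm\n",
              length(x$deviation), min(x$deviation), max(x$deviation)))
  invisible(x)
}

#' Classify deviations against a cutoff
#'
#' Strict three-way labelling: `plus` where deviation > +cutoff, `minus`
#' where deviation < -cutoff, `neutral` otherwise (deviations at exactly
#' +/- cutoff are neutral).  The default cutoff of 0.040 mm is the scanner
#' error bound derived from the sphere accuracy protocol (see
#' [derive_cutoff()]).
#'
#' @param field a `deviation_field` (or bare numeric vector).
#' @param cutoff_mm positive cutoff (mm).
#' @return factor with levels `minus`, `neutral`, `plus`.
#' @export
classify_deviation <- function(field, cutoff_mm = 0.040) {
  if (!is.numeric(cutoff_mm) || cutoff_mm <= 0)
    stop("cutoff must be a positive number (mm)")
  dev <- if (inherits(field, "deviation_field")) field$deviation else field
  lab <- ifelse(dev > cutoff_mm, "plus", ifelse(dev < -cutoff_mm, "minus", "neutral"))
  factor(lab, levels = c("minus", "neutral", "plus"))
}

#' Per-specimen deformation summary
#'
#' The six outcomes of the deviation analysis: maximum deviation, deformed
#' area and deformed volume, each in the + and - direction.  A triangle
#' belongs to a sign's region when the mean of its three vertex deviations
#' exceeds the cutoff in that direction; the region area is the sum of its
#' triangle areas and the volume integrates the per-triangle mean absolute
#' deviation over that area.
#'
#' @param field a `deviation_field`.
#' @param classes factor from [classify_deviation()] (same cutoff).
#' @param cutoff_mm the cutoff used for `classes` (mm).
#' @param area_mode `"surface"` (default; area measured on the mesh) or
#'   `"projected_z"` (footprint on the xy-plane).
#' @return object of class `deformation_summary`: named list with
#'   `max_dev_pos`, `max_dev_neg` (mm), `area_pos`, `area_neg` (mm^2),
#'   `vol_pos`, `vol_neg` (mm^3).
#' @export
deformation_summary <- function(field, classes = classify_deviation(field, cutoff_mm),
                                cutoff_mm = 0.040,
                                area_mode = c("surface", "projected_z")) {
  area_mode <- match.arg(area_mode)
  dev <- field$deviation
  mesh <- field$mesh
  f <- mesh$faces
  tri_mean <- (dev[f[, 1]] + dev[f[, 2]] + dev[f[, 3]]) / 3
  tri_mean_abs <- (abs(dev[f[, 1]]) + abs(dev[f[, 2]]) + abs(dev[f[, 3]])) / 3
  areas <- face_areas(mesh, area_mode)
  plus_tri <- tri_mean > cutoff_mm
  minus_tri <- tri_mean < -cutoff_mm
  max_pos <- if (any(classes == "plus")) max(dev[classes == "plus"]) else 0
  max_neg <- if (any(classes == "minus")) max(abs(dev[classes == "minus"])) else 0
  structure(list(
    max_dev_pos = max_pos,
    max_dev_neg = max_neg,
    area_pos = sum(areas[plus_tri]),
    area_neg = sum(areas[minus_tri]),
    vol_pos = sum(areas[plus_tri] * tri_mean_abs[plus_tri]),
    vol_neg = sum(areas[minus_tri] * tri_mean_abs[minus_tri])
  ), class = "deformation_summary", cutoff = cutoff_mm)
}

#' @export
print.deformation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<deformation_summary> (cutoff %.3f mm)\n",
    "  max deviation  +%.4f / -%.4f mm\n",
    "  deformed area   %.3f (+) / %.3f (-) mm^2\n",
    "  deformed volume %.4f (+) / %.4f (-) mm^3\n"),
    attr(x, "cutoff"), x$max_dev_pos, x$max_dev_neg,
    x$area_pos, x$area_neg, x$vol_pos, x$vol_neg))
  invisible(x)
}

#' Cross-sectional deviation profile
#'
#' Intersects the test mesh with a cutting plane and annotates the resulting
#' polyline(s) with the signed deviation interpolated linearly along the
#' crossed edges.  A sagittal section is a constant-x plane (normal
#' `c(1,0,0)`), a frontal section a constant-y plane.
#'
#' @param field a `deviation_field` on the aligned test mesh.
#' @param plane list with `point` (length-3) and `normal` (length-3).
#' @return object of class `cross_section`: list of polylines (longest
#'   first), each a data frame with `arc_length`, `x`, `y`, `z`,
#'   `deviation`; plus the plane.
#' @export
cross_section_deviation <- function(field, plane) {
  mesh <- field$mesh
  dev <- field$deviation
  n <- plane$normal / sqrt(sum(plane$normal^2))
  d <- as.numeric(mesh$vertices %*% n) - sum(plane$point * n)
  # nudge exact-zero vertices off the plane for robust crossing logic
  d[d == 0] <- 1e-12
  f <- mesh$faces
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) stop("cutting plane does not intersect the mesh")
  fc <- f[crossing, , drop = FALSE]

  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")
  edge_point <- function(i, j) {
    tt <- d[i] / (d[i] - d[j])
    list(p = mesh$vertices[i, , drop = FALSE] * (1 - tt) +
           mesh$vertices[j, , drop = FALSE] * tt,
         dev = dev[i] * (1 - tt) + dev[j] * tt)
  }
  seg_a <- character(0); seg_b <- character(0)
  pts <- list(); devs <- list()
  for (r in seq_len(nrow(fc))) {
    vv <- fc[r, ]
    dd <- d[vv]
    cross_edges <- list()
    for (e in list(c(1, 2), c(2, 3), c(1, 3))) {
      if (dd[e[1]] * dd[e[2]] < 0) cross_edges[[length(cross_edges) + 1L]] <- vv[e]
    }
    if (length(cross_edges) != 2L) next
    keys <- vapply(cross_edges, function(e) edge_key(e[1], e[2]), "")
    for (k in seq_along(keys)) {
      if (is.null(pts[[keys[k]]])) {
        ep <- edge_point(cross_edges[[k]][1], cross_edges[[k]][2])
        pts[[keys[k]]] <- ep$p
        devs[[keys[k]]] <- ep$dev
      }
    }
    seg_a <- c(seg_a, keys[1])
    seg_b <- c(seg_b, keys[2])
  }
  polylines <- chain_segments(seg_a, seg_b)
  out <- lapply(polylines, function(keys) {
    P <- do.call(rbind, pts[keys])
    dv <- unlist(devs[keys])
    arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    data.frame(arc_length = arc, x = P[, 1], y = P[, 2], z = P[, 3],
               deviation = dv)
  })
  lens <- vapply(out, function(p) max(p$arc_length), 0)
  structure(list(polylines = out[order(-lens)], plane = plane),
            class = "cross_section")
}

# chain undirected segments (key pairs) into ordered polylines
chain_segments <- function(a, b) {
  nodes <- unique(c(a, b))
  adj <- new.env(parent = emptyenv())
  for (k in seq_along(a)) {
    assign(a[k], c(mget(a[k], envir = adj, ifnotfound = list(NULL))[[1]], b[k]), envir = adj)
    assign(b[k], c(mget(b[k], envir = adj, ifnotfound = list(NULL))[[1]], a[k]), envir = adj)
  }
  visited <- new.env(parent = emptyenv())
  used_edge <- new.env(parent = emptyenv())
  ekey <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "~")
  polylines <- list()
  degree <- vapply(nodes, function(nd) length(get(nd, envir = adj)), 0L)
  # start walks at open ends first, then loops
  for (start in c(nodes[degree == 1L], nodes[degree != 1L])) {
    if (!is.null(mget(start, envir = visited, ifnotfound = list(NULL))[[1]])) next
    path <- start
    assign(start, TRUE, envir = visited)
    cur <- start
    repeat {
      nbrs <- get(cur, envir = adj)
      nxt <- NULL
      for (nb in nbrs) {
        ek <- ekey(cur, nb)
        if (is.null(mget(ek, envir = used_edge, ifnotfound = list(NULL))[[1]])) {
          nxt <- nb
          assign(ek, TRUE, envir = used_edge)
          break
        }
      }
      if (is.null(nxt)) break
      path <- c(path, nxt)
      assign(nxt, TRUE, envir = visited)
      cur <- nxt
    }
    if (length(path) > 1L) polylines[[length(polylines) + 1L]] <- path
  }
  polylines
}

#' Export a deviation colour map
#'
#' Writes an ASCII PLY with per-vertex colours on a continuous diverging
#' blue-green-red scale (negative deviation blue, zero green, positive red,
#' clamped at the display limit) plus the scalar deviation as a vertex
#' property, and a CSV (`vertex`, `x`, `y`, `z`, `deviation`, `class`)
#' alongside (same path with a `.csv` extension).
#'
#' @param field a `deviation_field`.
#' @param cutoff_mm cutoff used for the class column (mm).
#' @param path output `.ply` path.
#' @param display_limit colour scale clamp (mm); default 0.15.
#' @return the PLY path, invisibly.
#' @export
export_color_map <- function(field, cutoff_mm = 0.040, path,
                             display_limit = 0.15) {
  mesh <- field$mesh
  dev <- field$deviation
  classes <- classify_deviation(field, cutoff_mm)
  tt <- pmin(pmax(dev / display_limit, -1), 1)
  r <- ifelse(tt > 0, round(255 * tt), 0)
  g <- round(255 * (1 - abs(tt)))
  b <- ifelse(tt < 0, round(255 * -tt), 0)
  v <- mesh$vertices
  f <- mesh$faces
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write PLY to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               "property uchar red", "property uchar green", "property uchar blue",
               "property double quality",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g %d %d %d %.17g",
                     v[, 1], v[, 2], v[, 3], r, g, b, dev), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  csv_path <- paste0(sub("\\.ply$", "", path), ".csv")
  df <- data.frame(vertex = seq_len(nrow(v)),
                   x = v[, 1], y = v[, 2], z = v[, 3],
                   deviation = dev, class = as.character(classes))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   csv_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# colour triple of a deviation value on the export scale (used in tests)
color_map_rgb <- function(dev, display_limit = 0.15) {
  tt <- pmin(pmax(dev / display_limit, -1), 1)
  cbind(red = ifelse(tt > 0, round(255 * tt), 0),
        green = round(255 * (1 - abs(tt))),
        blue = ifelse(tt < 0, round(255 * -tt), 0))
}
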