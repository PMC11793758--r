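#' Triangle mesh constructor
#'
#' Builds the package's core geometry container: an indexed triangle surface
#' with coordinates in millimetres.  Faces are triples of 1-based vertex
#' indices; winding defines orientation (counter-clockwise seen from the
#' outside).  Meshes are open surfaces: no watertightness is required or
#' checked.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param normals optional numeric matrix, n x 3, per-vertex unit normals.
#' @param attributes optional named list of per-vertex vectors carried along
#'   by the synthetic generator (region labels, parameter coordinates).
#' @param validate logical; check invariants (finite coordinates, indices in
#'   range, unit normals).
#' @return an object of class `oca_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL, attributes = NULL,
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  m <- structure(list(vertices = vertices, faces = faces,
                      normals = normals, attributes = attributes),
                 class = "oca_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.oca_mesh <- function(x, ...) {
  bb <- bounding_box(x)
  cat(sprintf("<oca_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm\n",
              bb$min[1], bb$max[1], bb$min[2], bb$max[2], bb$min[3], bb$max[3]))
  invisible(x)
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L) stop("mesh has no vertices")
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
  }
  if (!is.null(mesh$normals)) {
    nrm <- sqrt(rowSums(mesh$normals^2))
    bad <- abs(nrm - 1) > 1e-9 & nrm > 0
    if (any(bad)) stop("vertex normals are not unit length")
  }
  invisible(TRUE)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh an `oca_mesh`.
#' @return list with `min` and `max` numeric length-3 vectors (mm).
#' @export
bounding_box <- function(mesh) {
  list(min = apply(mesh$vertices, 2, min),
       max = apply(mesh$vertices, 2, max))
}

# unit face normals and face areas, vectorised
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  area <- nrm / 2
  unit <- cr / ifelse(nrm > 0, nrm, 1)
  list(normal = unit, area = area, weighted = cr)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas, in mm^2.
#'
#' @param mesh an `oca_mesh`.
#' @return numeric scalar (mm^2).
#' @export
surface_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  sum(face_geometry(mesh)$area)
}

# per-face areas (mm^2); projected_z gives the area of the footprint on the
# xy-plane instead of the true surface area
face_areas <- function(mesh, mode = c("surface", "projected_z")) {
  mode <- match.arg(mode)
  fg <- face_geometry(mesh)
  if (mode == "surface") fg$area else abs(fg$weighted[, 3]) / 2
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the sum of incident face normals weighted by face
#' area, normalised to unit length.  Orientation follows the face winding.
#' Isolated vertices (no incident face) get a zero normal and are reported
#' via the `"isolated"` attribute.
#'
#' @param mesh an `oca_mesh`.
#' @return n x 3 matrix of unit normals (rows of isolated vertices are zero).
#' @export
compute_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L) stop("mesh has no vertices")
  acc <- matrix(0, nrow(v), 3)
  if (nrow(f) > 0L) {
    w <- face_geometry(mesh)$weighted  # cross product = 2 * area * unit normal
    for (k in 1:3) {
      s <- rowsum(w, group = f[, k], reorder = FALSE)
      idx <- as.integer(rownames(s))
      acc[idx, ] <- acc[idx, ] + s
    }
  }
  nrm <- sqrt(rowSums(acc^2))
  isolated <- nrm == 0
  out <- acc / ifelse(isolated, 1, nrm)
  attr(out, "isolated") <- which(isolated)
  out
}

round_key <- function(v, digits = 9L) {
  paste(round(v[, 1], digits), round(v[, 2], digits), round(v[, 3], digits),
        sep = "|")
}

# Merge duplicate vertices (exact match after rounding to 9 decimals) and
# drop degenerate faces (repeated index or area below 1e-14 mm^2).
clean_mesh <- function(vertices, faces, verbose = FALSE) {
  key <- round_key(vertices)
  first <- !duplicated(key)
  map <- match(key, key[first])
  merged <- sum(!first)
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(!degen)) {
    m <- triangle_mesh(vertices, faces[!degen, , drop = FALSE], validate = FALSE)
    zero <- face_areas(m) <= 1e-14
    degen[!degen][zero] <- TRUE
  }
  dropped <- sum(degen)
  faces <- faces[!degen, , drop = FALSE]
  if (verbose && (merged > 0L || dropped > 0L)) {
    message(sprintf("clean_mesh: merged %d duplicate vertices, dropped %d degenerate faces",
                    merged, dropped))
  }
  triangle_mesh(vertices, faces)
}

#' Read an STL file
#'
#' Reads binary or ASCII STL (auto-detected), merges duplicate vertices
#' (coordinates identical after rounding to 9 decimals, i.e. 1e-9 mm) into
#' shared indices and drops degenerate (zero-area) faces.  Coordinates are
#' taken to be millimetres.
#'
#' @param path path to an `.stl` file.
#' @param verbose log merge/drop counts.
#' @return an `oca_mesh`.
#' @export
read_stl <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop(sprintf("truncated STL file (only %d bytes): %s", size, path))
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(size, 512))
  close(con)
  ascii <- is_ascii_stl(head, size)
  raw_mesh <- if (ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  if (nrow(raw_mesh$vertices) == 0L) stop("empty mesh in STL file: ", path)
  mesh <- clean_mesh(raw_mesh$vertices, raw_mesh$faces, verbose = verbose)
  bad <- orientation_inconsistency(mesh)
  if (bad > 0.05) {
    message(sprintf("read_stl: %.1f%% of adjacent face pairs have opposing normals (inconsistent winding?): %s",
                    100 * bad, path))
  }
  mesh
}

# fraction of interior edges whose two incident faces disagree in
# orientation (normals differing by > 90 degrees across the shared edge)
orientation_inconsistency <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 2L) return(0)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nrow(f)), 3)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  shared <- key[-1] == key[-length(key)]
  if (!any(shared)) return(0)
  fa <- fid[-length(fid)][shared]
  fb <- fid[-1][shared]
  n <- face_geometry(mesh)$normal
  mean(rowSums(n[fa, , drop = FALSE] * n[fb, , drop = FALSE]) < 0)
}

is_ascii_stl <- function(head, size) {
  # byte-level checks: binary STL headers are arbitrary bytes
  printable <- head >= as.raw(0x20) & head <= as.raw(0x7e) |
    head %in% as.raw(c(0x09, 0x0a, 0x0d))
  if (!all(printable)) return(FALSE)
  txt <- rawToChar(head)
  starts_solid <- grepl("^\\s*solid", txt)
  if (!starts_solid) return(FALSE)
  # "solid" header is legal in binary STL too; check binary size consistency
  if (size >= 84) {
    n <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && size == 84 + 50 * as.double(n)) {
      # size-consistent binary; ASCII only if facet keyword present in head
      return(grepl("facet", txt))
    }
  }
  TRUE
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  expect <- 84 + 50 * as.double(n)
  if (size < expect) {
    stop(sprintf("truncated binary STL: %d facets declared need %.0f bytes, file has %d (stops at byte offset %d)",
                 n, expect, size, size))
  }
  body <- readBin(con, "raw", n = 50 * n)
  dim(body) <- c(50, n)
  # 12 floats (48 bytes) then attribute uint16
  floats <- readBin(as.vector(body[1:48, ]), "double", size = 4,
                    n = 12 * n, endian = "little")
  dim(floats) <- c(12, n)
  vs <- t(floats[4:12, , drop = FALSE])  # drop facet normal, keep 3 vertices
  vertices <- matrix(as.vector(t(vs)), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3 != 0L) {
    stop(sprintf("malformed ASCII STL (%d vertex lines, not a multiple of 3): %s",
                 length(vlines), path))
  }
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }, numeric(3)))
  if (any(!is.finite(nums))) stop("non-numeric vertex coordinates in ASCII STL: ", path)
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  list(vertices = nums, faces = faces)
}

#' Write an STL file
#'
#' @param mesh an `oca_mesh`.
#' @param path output path.
#' @param dialect `"binary"` (default, bit-stable for identical input) or
#'   `"ascii"`.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  fg <- face_geometry(mesh)
  n <- nrow(f)
  ok <- tryCatch({
    if (dialect == "binary") {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(as.raw(rep(0L, 80)), con)
      writeBin(as.integer(n), con, size = 4, endian = "little")
      tri <- cbind(fg$normal,
                   v[f[, 1], , drop = FALSE],
                   v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE])
      for (i in seq_len(n)) {
        writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
        writeBin(as.raw(c(0, 0)), con)
      }
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("solid ocamorph", con)
      for (i in seq_len(n)) {
        writeLines(sprintf("  facet normal %.9e %.9e %.9e",
                           fg$normal[i, 1], fg$normal[i, 2], fg$normal[i, 3]), con)
        writeLines("    outer loop", con)
        for (k in 1:3) {
          p <- v[f[i, k], ]
          writeLines(sprintf("      vertex %.9e %.9e %.9e", p[1], p[2], p[3]), con)
        }
        writeLines("    endloop", con)
        writeLines("  endfacet", con)
      }
      writeLines("endsolid ocamorph", con)
    }
    TRUE
  }, error = function(e) {
    stop("cannot write STL to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Read a whitespace-separated XYZ point list
#'
#' @param path text file with three numeric columns (mm); comment lines
#'   starting with `#` are skipped.
#' @return numeric matrix n x 3.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("x", "y", "z"))
  as.matrix(d)
}
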