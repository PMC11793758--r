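# fixtures and independent oracles used across the suite

# flat square patch in the z = 0 plane, counter-clockwise seen from +z,
# side length `size` mm, n x n quads
make_patch <- function(n = 10L, size = 10, z = 0) {
  g <- seq(0, size, length.out = n + 1L)
  V <- cbind(rep(g, each = n + 1L), rep(g, times = n + 1L), z)
  vid <- function(i, j) (i - 1L) * (n + 1L) + j
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  F <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
             cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  triangle_mesh(V, F)
}

# icosphere: subdivided icosahedron projected onto a sphere
make_icosphere <- function(subdiv = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (iter in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mget(key, envir = mid_cache, ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) return(hit)
      m <- (verts[[i]] + verts[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1L]] <<- m
      id <- length(verts)
      assign(key, id, envir = mid_cache)
      id
    }
    newF <- matrix(0L, 4L * nrow(F), 3L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4L * f - 3L, ] <- c(a, ab, ca)
      newF[4L * f - 2L, ] <- c(b, bc, ab)
      newF[4L * f - 1L, ] <- c(c, ca, bc)
      newF[4L * f, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, verts)
    F <- newF
  }
  triangle_mesh(V * radius, F)
}

# random rotation of at most max_deg about a random axis
rand_rotation <- function(max_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# --- independent oracle: closest point on a triangle -----------------------
# Minimises |a + s (b-a) + t (c-a) - p|^2 by solving the unconstrained
# normal equations and, when outside the simplex, comparing the three
# clamped edge minimisers.  Structurally unrelated to the compiled
# region-based routine it checks.
oracle_closest_on_triangle <- function(p, a, b, c) {
  e1 <- b - a; e2 <- c - a
  cand <- list()
  G <- matrix(c(sum(e1 * e1), sum(e1 * e2), sum(e1 * e2), sum(e2 * e2)), 2)
  rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
  st <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
  if (all(is.finite(st)) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
    cand <- c(cand, list(st))
  s1 <- min(max(sum(e1 * (p - a)) / sum(e1 * e1), 0), 1)
  s2 <- min(max(sum(e2 * (p - a)) / sum(e2 * e2), 0), 1)
  e3 <- c - b
  s3 <- min(max(sum(e3 * (p - b)) / sum(e3 * e3), 0), 1)
  cand <- c(cand, list(c(s1, 0)), list(c(0, s2)), list(c(1 - s3, s3)))
  best <- NULL; bestd <- Inf
  for (st in cand) {
    q <- a + st[1] * e1 + st[2] * e2
    d <- sqrt(sum((p - q)^2))
    if (d < bestd) { bestd <- d; best <- q }
  }
  list(point = best, distance = bestd)
}

# brute-force nearest point over all faces of a mesh
oracle_nearest <- function(mesh, p) {
  v <- mesh$vertices; f <- mesh$faces
  bestd <- Inf; best <- NULL
  for (k in seq_len(nrow(f))) {
    r <- oracle_closest_on_triangle(p, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
    if (r$distance < bestd) { bestd <- r$distance; best <- r$point }
  }
  list(point = best, distance = bestd)
}

# --- independent oracle: exact signed-rank p by explicit enumeration -------
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# one-triangle ASCII STL used by reader tests
write_single_triangle_ascii <- function(path) {
  writeLines(c("solid tri",
               "  facet normal 0 0 1",
               "    outer loop",
               "      vertex 0 0 0",
               "      vertex 1 0 0",
               "      vertex 0 1 0",
               "    endloop",
               "  endfacet",
               "endsolid tri"), path)
}

# unit cube as 12 facets with repeated corner coordinates (merge fixture)
make_cube_mesh <- function() {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces as vertex-index triples into `corners` (orientation irrelevant here)
  quads <- rbind(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6))
  tris <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  # expand to per-facet vertices (repeated corners), as an STL would store
  V <- corners[as.vector(t(tris)), ]
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  triangle_mesh(V, F)
}

small_arch <- function(resolution = 1.5, ...) {
  generate_arch_appliance(arch_params(resolution = resolution, ...))
}
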