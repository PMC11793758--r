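offset_patch_pair <- function(offset, n = 10L, size = 10) {
  ref <- make_patch(n, size = size)
  test <- ref
  test$vertices[, 3] <- test$vertices[, 3] + offset
  list(ref = ref, test = test)
}

test_that("signed deviation: zero for identical meshes, sign follows offset", {
  m <- make_patch(6)
  f0 <- signed_deviation_field(m, m)
  expect_equal(max(abs(f0$deviation)), 0)

  up <- offset_patch_pair(0.1)
  fu <- signed_deviation_field(up$test, up$ref)
  expect_equal(fu$deviation, rep(0.100, length(fu$deviation)), tolerance = 1e-9)

  dn <- offset_patch_pair(-0.07)
  fd <- signed_deviation_field(dn$test, dn$ref)
  expect_equal(fd$deviation, rep(-0.070, length(fd$deviation)), tolerance = 1e-9)
})

test_that("deviation field matches brute-force nearest distances", {
  ref <- small_arch(resolution = 2)
  test <- apply_deformation(ref, deformation_scenario(palatal_lift = 0.08,
                                                      buccal_retraction = 0.06))
  field <- signed_deviation_field(test, ref)
  set.seed(31)
  idx <- sample(nrow(test$vertices), 100)
  for (k in idx) {
    ref_d <- oracle_nearest(ref, test$vertices[k, ])$distance
    expect_lt(abs(abs(field$deviation[k]) - ref_d), 1e-12)
  }
})

test_that("classification uses strict inequalities at the cutoff", {
  dev <- c(0.05, -0.05, 0.039, -0.040)
  cl <- classify_deviation(dev, 0.040)
  expect_equal(as.character(cl), c("plus", "minus", "neutral", "neutral"))
  expect_true(all(classify_deviation(rep(0, 5), 0.04) == "neutral"))
  expect_error(classify_deviation(dev, 0), "positive")
})

test_that("closed-form summary of a uniformly offset patch", {
  pair <- offset_patch_pair(0.1, n = 10L, size = 10)
  field <- signed_deviation_field(pair$test, pair$ref)
  s <- deformation_summary(field, classify_deviation(field, 0.04),
                           cutoff_mm = 0.04)
  expect_equal(s$max_dev_pos, 0.1, tolerance = 1e-9)
  expect_equal(s$area_pos, 100, tolerance = 1e-9)
  expect_equal(s$vol_pos, 10, tolerance = 1e-9)
  expect_equal(s$max_dev_neg, 0)
  expect_equal(s$area_neg, 0)
  expect_equal(s$vol_neg, 0)
})

test_that("negating the field swaps the +/- outcomes exactly", {
  ref <- small_arch(resolution = 2)
  test <- apply_deformation(ref, deformation_scenario(palatal_lift = 0.09,
                                                      posterior_shrink = 0.07))
  field <- signed_deviation_field(test, ref)
  neg <- field
  neg$deviation <- -neg$deviation
  s1 <- deformation_summary(field, classify_deviation(field, 0.04), 0.04)
  s2 <- deformation_summary(neg, classify_deviation(neg, 0.04), 0.04)
  expect_equal(s1$max_dev_pos, s2$max_dev_neg)
  expect_equal(s1$area_pos, s2$area_neg)
  expect_equal(s1$vol_pos, s2$vol_neg)
  expect_equal(s1$max_dev_neg, s2$max_dev_pos)
  expect_equal(s1$area_neg, s2$area_pos)
  expect_equal(s1$vol_neg, s2$vol_pos)
})

test_that("half-offset patch brackets the boundary triangle row", {
  # left half (x < 5) offset +0.1, right half untouched; sharp boundary
  ref <- make_patch(10, size = 10)
  test <- ref
  left <- test$vertices[, 1] < 5 - 1e-9
  test$vertices[left, 3] <- test$vertices[left, 3] + 0.1
  field <- signed_deviation_field(test, ref)
  s <- deformation_summary(field, classify_deviation(field, 0.04), 0.04)
  # boundary column of quads spans x in [4,5]: 10 mm^2 of mixed triangles
  expect_gte(s$area_pos, 40)
  expect_lte(s$area_pos, 50 + 1e-9)
  expect_lte(s$vol_pos, 0.1 * s$area_pos + 1e-9)
  expect_gte(s$vol_pos, 0.1 * (s$area_pos - 10) - 1e-9)
})

test_that("cutoff monotonicity and volume bounds on randomized fields", {
  mesh <- make_patch(8, size = 10)
  set.seed(17)
  for (rep in 1:50) {
    field <- structure(list(deviation = stats::rnorm(nrow(mesh$vertices), 0, 0.08),
                            mesh = mesh), class = "deviation_field")
    cuts <- sort(stats::runif(3, 0.01, 0.15))
    prev <- NULL
    for (cutoff in cuts) {
      s <- deformation_summary(field, classify_deviation(field, cutoff), cutoff)
      for (sign in c("pos", "neg")) {
        a <- s[[paste0("area_", sign)]]
        v <- s[[paste0("vol_", sign)]]
        mx <- s[[paste0("max_dev_", sign)]]
        expect_gte(v, cutoff * a - 1e-12)
        if (a > 0) expect_lte(v, mx * a + 1e-12)
      }
      if (!is.null(prev)) {
        expect_lte(s$area_pos, prev$area_pos + 1e-12)
        expect_lte(s$area_neg, prev$area_neg + 1e-12)
        expect_lte(s$vol_pos, prev$vol_pos + 1e-12)
        expect_lte(s$vol_neg, prev$vol_neg + 1e-12)
      }
      prev <- s
    }
    # max deviations do not depend on the cutoff while any vertex qualifies
    s1 <- deformation_summary(field, classify_deviation(field, 0.01), 0.01)
    s2 <- deformation_summary(field, classify_deviation(field, 0.02), 0.02)
    if (s2$max_dev_pos > 0) expect_equal(s1$max_dev_pos, s2$max_dev_pos)
    if (s2$max_dev_neg > 0) expect_equal(s1$max_dev_neg, s2$max_dev_neg)
  }
})

test_that("projected-area mode measures the xy footprint", {
  # tilted patch: surface area exceeds its footprint by 1/cos(angle)
  ref <- make_patch(5, size = 10)
  tilt <- pi / 6
  Rx <- matrix(c(1, 0, 0, 0, cos(tilt), sin(tilt), 0, -sin(tilt), cos(tilt)), 3)
  ref_t <- apply_transform(ref, rigid_transform(Rx, c(0, 0, 0)))
  test_t <- ref_t
  nrm <- compute_vertex_normals(ref_t)
  test_t$vertices <- test_t$vertices + 0.1 * nrm
  field <- signed_deviation_field(test_t, ref_t)
  s_surf <- deformation_summary(field, classify_deviation(field, 0.04), 0.04,
                                area_mode = "surface")
  s_proj <- deformation_summary(field, classify_deviation(field, 0.04), 0.04,
                                area_mode = "projected_z")
  expect_equal(s_surf$area_pos, 100, tolerance = 1e-6)
  expect_equal(s_proj$area_pos, 100 * cos(tilt), tolerance = 1e-6)
})

test_that("cross-section: constant profile on an offset patch, miss errors", {
  pair <- offset_patch_pair(0.1, n = 10L, size = 10)
  field <- signed_deviation_field(pair$test, pair$ref)
  cs <- cross_section_deviation(field, list(point = c(5, 5, 0),
                                            normal = c(1, 0, 0)))
  prof <- cs$polylines[[1]]
  expect_gt(nrow(prof), 5)
  expect_true(all(diff(prof$arc_length) > 0))
  expect_equal(prof$deviation, rep(0.1, nrow(prof)), tolerance = 1e-9)
  expect_equal(max(prof$arc_length), 10, tolerance = 1e-9)
  expect_error(cross_section_deviation(field, list(point = c(50, 0, 0),
                                                   normal = c(1, 0, 0))),
               "does not intersect")
})

test_that("frontal section through the lifted zone recovers the lift", {
  ref <- small_arch(resolution = 1)
  lift <- 0.08
  test <- apply_deformation(ref, deformation_scenario(palatal_lift = lift))
  field <- signed_deviation_field(test, ref)
  # cut at the y of the peak-lift vertex (molar region)
  peak <- which.max(test$vertices[, 3] - ref$vertices[, 3])
  cs <- cross_section_deviation(field, list(point = test$vertices[peak, ],
                                            normal = c(0, 1, 0)))
  best <- max(vapply(cs$polylines, function(p) max(p$deviation), 0))
  expect_gt(best, lift - 0.01)
  expect_lte(best, lift + 1e-6)
})

test_that("colour map export: endpoint colours and CSV round trip", {
  pair <- offset_patch_pair(0.0, n = 4L)
  field <- signed_deviation_field(pair$test, pair$ref)
  rgb0 <- ocamorph:::color_map_rgb(0)
  expect_equal(unname(rgb0[1, ]), c(0, 255, 0))
  expect_equal(unname(ocamorph:::color_map_rgb(0.15)[1, ]), c(255, 0, 0))
  expect_equal(unname(ocamorph:::color_map_rgb(-0.15)[1, ]), c(0, 0, 255))
  expect_equal(unname(ocamorph:::color_map_rgb(9)[1, ]), c(255, 0, 0))

  ref <- small_arch(resolution = 2)
  test <- apply_deformation(ref, deformation_scenario(palatal_lift = 0.09))
  field <- signed_deviation_field(test, ref)
  ply <- withr::local_tempfile(fileext = ".ply")
  export_color_map(field, 0.04, ply)
  lines <- readLines(ply)
  expect_equal(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines, value = TRUE)))
  expect_equal(nv, nrow(test$vertices))
  csv <- read.csv(sub("\\.ply$", ".csv", ply))
  expect_identical(csv$deviation, field$deviation)
  expect_equal(nrow(csv), nrow(test$vertices))
  expect_true(all(csv$class %in% c("minus", "neutral", "plus")))
})
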