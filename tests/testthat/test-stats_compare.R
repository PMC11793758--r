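test_that("extreme n=8 case: all positive differences give p = 2/256", {
  x <- c(5, 6, 7, 8, 9, 10, 11, 12)
  y <- x - c(1, 2, 3, 4, 5, 6, 7, 8) / 10
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, 36)
  expect_equal(res$p_value, 0.0078125)
  expect_equal(res$method, "exact")
})

test_that("tied magnitudes {+1, -1} give p = 1", {
  res <- wilcoxon_signed_rank(c(1, 0), c(0, 1))
  expect_equal(res$p_value, 1)
  expect_true(res$ties)
})

test_that("mixed ties match the brute-force enumeration oracle", {
  d <- c(3, -1, 2, -2, 1, -3)
  res <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_equal(res$p_value, oracle_signed_rank_p(d, rep(0, 6)))
})

test_that("exact p equals enumeration oracle over random datasets (n <= 10)", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    # mix of continuous and tied integer differences, some zeros
    d <- if (stats::runif(1) < 0.5) {
      sample(-4:4, n, replace = TRUE)
    } else {
      round(stats::rnorm(n, 0.3, 1), 1)
    }
    if (all(d == 0)) d[1] <- 1
    x <- stats::rnorm(n)
    y <- x - d
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_value, oracle_signed_rank_p(x, y),
                 tolerance = 1e-12,
                 label = paste("p for d =", paste(d, collapse = ",")))
  }
})

test_that("antisymmetry: swapping samples mirrors W, keeps p", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    if (all(x == y)) next
    a <- wilcoxon_signed_rank(x, y)
    b <- wilcoxon_signed_rank(y, x)
    expect_equal(a$statistic + b$statistic, a$n * (a$n + 1) / 2)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("p is invariant under monotone transforms of the magnitudes", {
  set.seed(77)
  x <- stats::rnorm(9)
  y <- stats::rnorm(9)
  d <- x - y
  p0 <- wilcoxon_signed_rank(x, y)$p_value
  # order-preserving transform of |d| keeping signs: d' = sign(d) * exp(|d|)
  d2 <- sign(d) * exp(abs(d))
  p1 <- wilcoxon_signed_rank(d2, rep(0, 9))$p_value
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("agreement with stats::wilcox.test on tie-free data", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    theirs <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(theirs$p.value), tolerance = 1e-12)
  }
})

test_that("zero differences: drop-zeros default and Pratt variant", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 2)  # two zero differences
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$n, 2L)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "no nonzero differences")
  pr <- wilcoxon_signed_rank(x, y, zero_method = "pratt")
  expect_equal(pr$n, 2L)
  # Pratt ranks |d| with zeros included: |d| = (0,0,1,2) -> nonzero ranks 3, 4
  expect_equal(pr$statistic, 7)
})

test_that("large-n normal approximation is close to the exact path", {
  set.seed(2)
  x <- stats::rnorm(25, 0.4)
  y <- stats::rnorm(25)
  appr <- wilcoxon_signed_rank(x, y)  # n = 25 -> normal approx
  expect_equal(appr$method, "normal-approx")
  ex <- wilcoxon_signed_rank(x, y, exact_limit = 25L)
  expect_equal(ex$method, "exact")
  # far-tail p-values: the corrected normal approximation tracks the exact
  # value to within a factor of ~1.5
  expect_lt(abs(log(appr$p_value) - log(ex$p_value)), log(1.5))
  expect_equal(appr$p_value < 0.05, ex$p_value < 0.05)
})

test_that("compare_conditions: extreme case, medians, error capture", {
  cols <- c("max_dev_neg", "max_dev_pos", "area_neg", "area_pos",
            "vol_neg", "vol_pos")
  set.seed(6)
  W <- as.data.frame(matrix(stats::runif(48, 0.05, 0.08), 8,
                            dimnames = list(NULL, cols)))
  D <- W + 0.05  # strictly greater on every outcome
  po <- paired_outcomes(1:8, W, D)
  tab <- compare_conditions(po)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$p_value, rep(0.0078125, 6))
  # median convention: mean of the 4th and 5th order statistics at n = 8
  m1 <- sort(W$area_pos)
  expect_equal(tab$W_median[tab$outcome == "area_pos"], mean(m1[4:5]))

  tab2 <- compare_conditions(paired_outcomes(1:8, W, W))
  expect_true(all(is.na(tab2$p_value)))
  expect_true(all(grepl("no nonzero differences", tab2$note)))

  expect_error(paired_outcomes(1:3, W[1:2, ], D[1:2, ]), "one row per specimen")
  expect_error(compare_conditions(paired_outcomes(1, W[1, ], D[1, ])),
               "at least 2")
})

test_that("power of the paired design over 50 experiment replicates", {
  # Simulation-derived regression: in the stated world (8 specimens, fixed
  # W ~0.07 / D ~0.12 magnitudes, 0.0279 mm scan noise on every scan,
  # 1.8 mm resolution, seeds 1001..1050) the observed all-six rejection rate
  # is 0.36: area and volume outcomes reject at 0.98-1.00 while the
  # max-deviation outcomes are diluted by the noise-field maximum.  The
  # observed rates are frozen as the regression bands.
  rates <- matrix(NA, 50, 6)
  for (rep in 1:50) {
    cfg <- build_config(list(
      arch = list(span = 50, depth = 40, band_width = 8,
                  occlusal_height = 3, resolution = 1.8),
      specimen_variation = 0,
      seed = 1000L + rep))
    sim <- simulate_experiment(cfg)
    rates[rep, ] <- sim$comparison$p_value < 0.05
  }
  expect_gte(mean(apply(rates, 1, all)), 0.25)
  per_outcome <- colMeans(rates)
  names(per_outcome) <- sim$comparison$outcome
  expect_gte(per_outcome[["area_neg"]], 0.9)
  expect_gte(per_outcome[["area_pos"]], 0.9)
  expect_gte(per_outcome[["vol_neg"]], 0.9)
  expect_gte(per_outcome[["vol_pos"]], 0.9)
})

test_that("outcomes CSV round trip feeds compare_conditions", {
  cols <- c("max_dev_neg", "max_dev_pos", "area_neg", "area_pos",
            "vol_neg", "vol_pos")
  set.seed(3)
  W <- as.data.frame(matrix(stats::runif(18), 3, dimnames = list(NULL, cols)))
  D <- as.data.frame(matrix(stats::runif(18), 3, dimnames = list(NULL, cols)))
  path <- withr::local_tempfile(fileext = ".csv")
  long <- rbind(cbind(specimen = 1:3, condition = "W", W),
                cbind(specimen = 1:3, condition = "D", D))
  utils::write.csv(long, path, row.names = FALSE)
  po <- read_outcomes_csv(path)
  expect_equal(po$W$area_pos, W$area_pos)
  expect_equal(po$D$vol_neg, D$vol_neg)
  expect_s3_class(compare_conditions(po), "data.frame")
})
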