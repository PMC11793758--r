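#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Differences d = x - y are formed, zero differences are dropped
#' (Wilcoxon's convention; Pratt's zero-rank method is available), absolute
#' differences are ranked with average ranks for ties, and the statistic W
#' is the sum of the ranks of the positive differences.  For n <= 20 the
#' two-sided p-value is exact, computed on the realised rank multiset by
#' enumerating the 2^n sign assignments (through a generating-function
#' convolution); for larger n a normal approximation with tie and continuity
#' corrections is used.  The exact two-sided p is
#' 2 * min(P(W <= w), P(W >= w)), capped at 1.
#'
#' This differs from [stats::wilcox.test()], whose exact path refuses ties;
#' here the exact null distribution is conditioned on the observed (possibly
#' tied) ranks, the convention needed for small paired designs.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"` (rank
#'   with zeros included, then drop the zero ranks).
#' @param exact_limit use exact enumeration for n (after zero removal) up to
#'   this value (default 20).
#' @return object of class `wilcoxon_result`: list with `n` (pairs used),
#'   `statistic` (W), `p_value`, `method` (`"exact"` or `"normal-approx"`),
#'   `ties` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("wilcox", "pratt"),
                                 exact_limit = 20L) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  d <- x - y
  if (all(d == 0)) stop("no nonzero differences")
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
  } else {
    ranks_all <- rank(abs(d))
    ranks <- ranks_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  W <- sum(ranks[d > 0])
  ties <- anyDuplicated(ranks) > 0L
  if (n <= exact_limit) {
    p <- exact_signed_rank_p(ranks, W)
    method <- "exact"
  } else {
    p <- normal_signed_rank_p(ranks, W)
    method <- "normal-approx"
  }
  structure(list(n = n, statistic = W, p_value = p, method = method,
                 ties = ties),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> n = %d, W = %g, p = %.6g (%s%s)\n",
              x$n, x$statistic, x$p_value, x$method,
              if (x$ties) ", ties" else ""))
  invisible(x)
}

# Exact two-sided p for the signed-rank statistic given the realised rank
# multiset.  Average ranks are multiples of 1/2, so doubled ranks are
# integers and the 2^n sign assignments collapse to a polynomial product:
# each rank contributes a factor (1 + z^(2r)).
exact_signed_rank_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[k + 1] = #assignments with 2W == k
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  w2 <- round(2 * W)
  idx <- seq_along(counts) - 1L
  p_le <- sum(counts[idx <= w2 + 1e-9])
  p_ge <- sum(counts[idx >= w2 - 1e-9])
  min(1, 2 * min(p_le, p_ge) / sum(counts))
}

# normal approximation with tie correction and continuity correction
normal_signed_rank_p <- function(ranks, W) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  tab <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  sigma <- sqrt(sigma2)
  z <- (W - mu - sign(W - mu) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Paired outcomes table
#'
#' Bundles the six deformation outcomes of every specimen under the two
#' storage conditions.
#'
#' @param specimens character or integer specimen ids.
#' @param W,D data frames (one row per specimen, same order as `specimens`)
#'   with columns `max_dev_neg`, `max_dev_pos`, `area_neg`, `area_pos`,
#'   `vol_neg`, `vol_pos` — e.g. built from [deformation_summary()] objects
#'   via [summary_row()].
#' @return object of class `paired_outcomes`.
#' @export
paired_outcomes <- function(specimens, W, D) {
  cols <- c("max_dev_neg", "max_dev_pos", "area_neg", "area_pos",
            "vol_neg", "vol_pos")
  if (!all(cols %in% names(W)) || !all(cols %in% names(D)))
    stop("W and D must contain the six outcome columns: ",
         paste(cols, collapse = ", "))
  if (nrow(W) != length(specimens) || nrow(D) != length(specimens))
    stop("W and D must have one row per specimen")
  structure(list(specimens = specimens,
                 W = W[, cols], D = D[, cols]),
            class = "paired_outcomes")
}

#' Flatten a deformation summary into a one-row data frame
#' @param s a `deformation_summary`.
#' @return one-row data frame with the six outcome columns.
#' @export
summary_row <- function(s) {
  data.frame(max_dev_neg = s$max_dev_neg, max_dev_pos = s$max_dev_pos,
             area_neg = s$area_neg, area_pos = s$area_pos,
             vol_neg = s$vol_neg, vol_pos = s$vol_pos)
}

#' Compare storage conditions outcome by outcome
#'
#' Runs the paired Wilcoxon signed-rank test (D vs W) for each of the six
#' outcomes, with per-group medians and quartiles.  No multiplicity
#' adjustment is applied across the six outcomes.  A failing test (e.g. no
#' nonzero differences) is recorded in the `note` column rather than
#' aborting the table.
#'
#' @param paired a [paired_outcomes()] object (at least 2 specimens).
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return data frame with one row per outcome: medians and quartiles of
#'   both groups, n, W statistic, p-value, method, note.
#' @export
compare_conditions <- function(paired, ...) {
  stopifnot(inherits(paired, "paired_outcomes"))
  if (length(paired$specimens) < 2L) stop("need at least 2 specimens")
  cols <- names(paired$W)
  rows <- lapply(cols, function(col) {
    w <- paired$W[[col]]
    d <- paired$D[[col]]
    qw <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
    qd <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    res <- tryCatch(wilcoxon_signed_rank(d, w, ...), error = function(e) e)
    failed <- inherits(res, "error")
    data.frame(outcome = col,
               n = length(w),
               W_median = qw[2], W_q1 = qw[1], W_q3 = qw[3],
               D_median = qd[2], D_q1 = qd[1], D_q3 = qd[3],
               statistic = if (failed) NA_real_ else res$statistic,
               p_value = if (failed) NA_real_ else res$p_value,
               method = if (failed) NA_character_ else res$method,
               note = if (failed) conditionMessage(res) else "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
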