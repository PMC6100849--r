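#' Kinship association tests
#'
#' Small wrappers returning a uniform test-result structure (`statistic`,
#' `df`, `p_value`, `n`) for the association analyses: goodness-of-fit
#' chi-squared against an equal split, 2x2 independence chi-squared,
#' Spearman rank correlation, and the Mann-Whitney U test.
#'
#' @name assoc_tests
NULL

test_result <- function(name, statistic, df = NA_real_, p_value, n,
                        method = name, note = NULL) {
  out <- list(name = name, statistic = unname(statistic), df = unname(df),
              p_value = unname(p_value), n = n, method = method, note = note)
  class(out) <- "assoc_test"
  out
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.5g%s, p = %.4g (n = %s)\n", x$method,
              x$statistic,
              if (is.finite(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value, paste(x$n, collapse = "/")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname assoc_tests
#' @param k1,k2 counts in the two categories.
#' @return an `assoc_test` list.
#' @examples
#' chisq_equal_split(57, 52)
#' @export
chisq_equal_split <- function(k1, k2) {
  stopifnot(is_count(k1, 0), is_count(k2, 0), k1 + k2 > 0)
  ht <- stats::chisq.test(c(k1, k2), p = c(0.5, 0.5))
  test_result("chisq_equal_split", ht$statistic, ht$parameter, ht$p.value,
              n = k1 + k2, method = "Chi-squared goodness of fit (equal split)")
}

#' @rdname assoc_tests
#' @param tab a 2x2 matrix of counts.
#' @param yates apply Yates' continuity correction?
#' @export
chisq_independence <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("chisq_independence: degenerate table (zero marginal)")
  ht <- stats::chisq.test(tab, correct = yates)
  test_result("chisq_independence", ht$statistic, ht$parameter, ht$p.value,
              n = sum(tab),
              method = sprintf("Pearson chi-squared (2x2%s)",
                               if (yates) ", Yates-corrected" else ""))
}

#' @rdname assoc_tests
#' @param x,y numeric vectors of equal length (>= 3). Ties get midranks; the
#'   two-sided p-value uses the t approximation with n - 2 df.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("spearman_test: correlation undefined for a zero-variance vector")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ht$estimate)
  test_result("spearman", rho, df = length(x) - 2, ht$p.value, n = length(x),
              method = "Spearman rank correlation (t approximation)")
}

# U statistic of sample a against b: #{(i,j): a_i > b_j} + ties/2
u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' @rdname assoc_tests
#' @param a,b the two samples (both nonempty). The reported statistic is
#'   `min(U_a, U_b)`. For `length(a) * length(b) <= max_exact` the two-sided
#'   p-value is computed by exact enumeration of all group assignments
#'   (valid under ties); otherwise the normal approximation with tie
#'   correction is used.
#' @param max_exact pair-count bound below which exact enumeration is used.
#' @export
mann_whitney <- function(a, b, max_exact = 400) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b)
  ua <- u_stat(a, b)
  u <- min(ua, na * nb - ua)
  # exact enumeration must also be combinatorially feasible: C(na+nb, na)
  # explodes for balanced mid-sized groups even when na*nb is small
  if (na * nb <= max_exact && choose(na + nb, na) <= 2e5) {
    # enumerate all C(na+nb, na) assignments of the pooled values to group a
    pool <- c(a, b)
    r <- rank(pool)
    splits <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    us <- pmin(us, na * nb - us)
    p <- mean(us <= u + 1e-9)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    p <- ht$p.value
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  test_result("mann_whitney", u, df = NA_real_, p, n = c(na, nb),
              method = method)
}

not_computable <- function(name, why, n = 0) {
  test_result(name, NA_real_, NA_real_, NA_real_, n = n,
              method = name, note = paste("not computable:", why))
}

#' Bundle of Darwin's-naturalization-hypothesis association tests
#'
#' Runs the kinship test battery on a spread classification: equal-split
#' chi-squared of with- vs without-relatives counts within the widespread
#' (ML) and limited-spread (FL) sets, the 2x2 independence test of spread
#' class by relative presence, Spearman correlations of congener counts
#' against regression residuals within the with-relatives strata, and
#' Mann-Whitney comparisons of locality counts between species with and
#' without relatives, overall and (optionally) within ordination groups.
#' Strata that are empty or too small yield a "not computable" row rather
#' than an error.
#'
#' @param classification a `spread_classification` with an `n_relatives`
#'   column (as produced from profiles carrying congener counts).
#' @param groups optional named vector/factor of group labels (e.g. NMDS
#'   K-means groups), named by species, for per-group Mann-Whitney tests.
#' @return a `dnh_report` data frame: one row per test with `test`,
#'   `stratum`, `statistic`, `df`, `p_value`, `n`, `note`.
#' @export
dnh_tests <- function(classification, groups = NULL) {
  stopifnot(inherits(classification, "spread_classification"),
            "n_relatives" %in% names(classification))
  cl <- classification
  has_rel <- cl$n_relatives > 0
  rows <- list()
  add <- function(tr, stratum) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = tr$name, stratum = stratum, statistic = tr$statistic,
      df = tr$df, p_value = tr$p_value, n = sum(tr$n),
      note = if (is.null(tr$note)) "" else tr$note,
      stringsAsFactors = FALSE)
  }

  for (lab in c("ML", "FL")) {
    k1 <- sum(cl$label == lab & has_rel)
    k2 <- sum(cl$label == lab & !has_rel)
    add(if (k1 + k2 > 0) chisq_equal_split(k1, k2) else
      not_computable("chisq_equal_split", "empty stratum"), lab)
  }

  tab <- rbind(ML = c(with = sum(cl$label == "ML" & has_rel),
                      without = sum(cl$label == "ML" & !has_rel)),
               FL = c(with = sum(cl$label == "FL" & has_rel),
                      without = sum(cl$label == "FL" & !has_rel)))
  add(tryCatch(chisq_independence(tab),
               error = function(e) not_computable("chisq_independence",
                                                  conditionMessage(e))),
      "ML/FL x relatives")

  for (lab in c("ML", "FL")) {
    sel <- cl$label == lab & has_rel
    add(if (sum(sel) >= 3 && stats::sd(cl$n_relatives[sel]) > 0 &&
            stats::sd(cl$residual[sel]) > 0)
      spearman_test(cl$n_relatives[sel], cl$residual[sel]) else
        not_computable("spearman", "stratum too small or constant",
                       n = sum(sel)),
      paste0(lab, " with relatives"))
  }

  post_lag <- cl$label %in% c("ML", "FL", "EXPECTED")
  a <- cl$n_localities[post_lag & has_rel]
  b <- cl$n_localities[post_lag & !has_rel]
  add(if (length(a) && length(b)) mann_whitney(a, b) else
    not_computable("mann_whitney", "empty stratum",
                   n = length(a) + length(b)), "all post-lag")

  if (!is.null(groups)) {
    g <- groups[cl$species]
    for (lev in sort(unique(stats::na.omit(as.character(g))))) {
      sel <- !is.na(g) & g == lev & post_lag
      a <- cl$n_localities[sel & has_rel]
      b <- cl$n_localities[sel & !has_rel]
      add(if (length(a) && length(b)) mann_whitney(a, b) else
        not_computable("mann_whitney", "empty stratum",
                       n = length(a) + length(b)),
        paste("group", lev))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dnh_report", "data.frame")
  out
}
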