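#' Group-comparison statistics
#'
#' The study's group comparisons reduce to a handful of classical tests:
#' Fisher's exact test on 2x2 outcome tables (re-entry vs failed re-entry,
#' rapid vs delayed calcium responders), rank tests (Mann-Whitney,
#' Kruskal-Wallis) for migration distances and shiver percentages,
#' Brown-Forsythe and Welch ANOVA for invadopodia durations, paired t for
#' within-animal condition contrasts, and Pearson chi-squared for
#' categorical event-class counts. Each returns a `test_result`.
#'
#' @name regenquant-stats
NULL

#' Construct a test result record
#'
#' @param test_name character scalar naming the test.
#' @param statistic numeric test statistic, or `NA` when the test has none.
#' @param p_value p-value in \[0, 1\].
#' @param group_ns integer vector of per-group sizes.
#' @param alpha nominal significance level (the study used 0.05 throughout).
#' @param ... extra named fields (degrees of freedom, flags) carried along.
#' @return A list of class `test_result`.
#' @export
test_result <- function(test_name, statistic, p_value, group_ns,
                        alpha = 0.05, ...) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(test_name = test_name, statistic = statistic,
         p_value = min(p_value, 1), group_ns = group_ns, alpha = alpha, ...),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g (n = %s)\n", x$test_name,
              format(x$statistic, digits = 4), x$p_value,
              paste(x$group_ns, collapse = ", ")))
  invisible(x)
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("table has no observations")
  storage.mode(m) <- "double"
  m
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-ordering rule: with margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (a relative slack
#' of 1e-7 guards against floating-point ties, as mainstream packages do).
#' Rows are groups, columns are outcome / failed outcome.
#'
#' @param table 2x2 matrix of counts, or a vector `c(a, b, c, d)` read
#'   row-wise.
#' @return A `test_result` with the sample odds ratio as the statistic.
#' @examples
#' # 1/8 mock-ablated vs 2/18 non-ablated re-entry: p = 1
#' fisher_exact(matrix(c(1, 7, 2, 16), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  if (is.vector(table) && length(table) == 4L) {
    table <- matrix(table, 2L, 2L, byrow = TRUE)
  }
  m <- as_2x2(table)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  test_result("Fisher's exact test (two-sided)", statistic = or,
              p_value = min(1, p), group_ns = rowSums(m))
}

#' Rank-based group comparisons
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis H for two or more, with
#' mid-rank handling of ties. When every value across all groups is
#' identical the rank statistics are degenerate; p = 1 is returned with a
#' warning rather than NaN.
#'
#' @param groups list of numeric vectors, one per group (each non-empty).
#' @param force_kruskal use Kruskal-Wallis even for two groups.
#' @return A `test_result`.
#' @export
rank_tests <- function(groups, force_kruskal = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 1L)) stop("each group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    warning("all values identical across groups; rank test degenerate")
    nm <- if (length(groups) == 2L && !force_kruskal) "Mann-Whitney U" else
      "Kruskal-Wallis H"
    return(test_result(nm, statistic = NA_real_, p_value = 1,
                       group_ns = lengths(groups), degenerate = TRUE))
  }
  if (length(groups) == 2L && !force_kruskal) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                              exact = FALSE, correct = FALSE))
    test_result("Mann-Whitney U", statistic = unname(wt$statistic),
                p_value = wt$p.value, group_ns = lengths(groups))
  } else {
    kt <- stats::kruskal.test(x, g)
    test_result("Kruskal-Wallis H", statistic = unname(kt$statistic),
                p_value = kt$p.value, group_ns = lengths(groups),
                df = unname(kt$parameter))
  }
}

#' Welch and Brown-Forsythe ANOVA for unequal-variance group means
#'
#' The invadopodia duration compilations were compared with
#' "Brown-Forsythe and Welch ANOVA". Both tests of equality of group means
#' are computed: Welch's ANOVA (variance-weighted grand mean,
#' Welch-Satterthwaite denominator df) and the Brown-Forsythe F* statistic
#' (unweighted grand mean, per-group variances in the denominator with its
#' standard df correction). A zero-variance group is handled by the
#' formulas as written and flagged.
#'
#' @param groups list of numeric vectors, each with >= 2 values.
#' @return list with elements `welch` and `brown_forsythe`, both `test_result`s.
#' @export
variance_tests <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs at least two values")
  ni <- lengths(groups)
  mi <- vapply(groups, mean, 0)
  vi <- vapply(groups, stats::var, 0)
  k <- length(groups); N <- sum(ni)
  zero_var <- any(vi == 0)

  # Welch ANOVA
  wi <- ni / vi
  if (all(is.finite(wi))) {
    mw <- sum(wi * mi) / sum(wi)
    A <- sum(wi * (mi - mw)^2) / (k - 1)
    S <- sum((1 - wi / sum(wi))^2 / (ni - 1))
    Fw <- A / (1 + 2 * (k - 2) * S / (k^2 - 1))
    df2w <- (k^2 - 1) / (3 * S)
    pw <- stats::pf(Fw, k - 1, df2w, lower.tail = FALSE)
  } else {
    Fw <- Inf; df2w <- NA_real_; pw <- 0
  }
  welch <- test_result("Welch ANOVA", statistic = Fw, p_value = pw,
                       group_ns = ni, df1 = k - 1, df2 = df2w,
                       zero_variance_group = zero_var)

  # Brown-Forsythe F*
  mg <- mean(unlist(groups, use.names = FALSE))
  num <- sum(ni * (mi - mg)^2)
  den_terms <- (1 - ni / N) * vi
  den <- sum(den_terms)
  if (den > 0) {
    Fbf <- num / den
    ci <- den_terms / den
    df2 <- 1 / sum(ci^2 / (ni - 1))
    pbf <- stats::pf(Fbf, k - 1, df2, lower.tail = FALSE)
  } else {
    Fbf <- if (num > 0) Inf else NA_real_
    df2 <- NA_real_
    pbf <- if (num > 0) 0 else 1
  }
  bf <- test_result("Brown-Forsythe ANOVA", statistic = Fbf, p_value = pbf,
                    group_ns = ni, df1 = k - 1, df2 = df2,
                    zero_variance_group = zero_var)
  list(welch = welch, brown_forsythe = bf)
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors of equal length >= 2 (one pair per
#'   animal across the two water conditions).
#' @return A `test_result` with per-pair deltas attached.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    tt_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
    return(test_result("Paired t-test", statistic = tt_stat, p_value = p,
                       group_ns = length(x), deltas = d, df = length(x) - 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result("Paired t-test", statistic = unname(tt$statistic),
              p_value = tt$p.value, group_ns = length(x),
              df = unname(tt$parameter), deltas = d)
}

#' Pearson chi-squared test on an R x C count table
#'
#' Uncorrected (no Yates continuity correction), so the 2x2 statistic equals
#' the closed form N (ad - bc)^2 / (r1 r2 c1 c2).
#'
#' @param table matrix of counts.
#' @return A `test_result`.
#' @export
chisq_test <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("table has an empty margin")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_result("Pearson chi-squared", statistic = unname(ct$statistic),
              p_value = ct$p.value, group_ns = rowSums(m),
              df = unname(ct$parameter))
}
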