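# Floral trait integration: all-pairs Pearson correlation censuses, pair
# counting, percent-significant summaries, one-way F comparison of |PCC|
# distributions, and the terpenoid-carotenoid tradeoff correlation.

#' Number of unordered trait pairs
#'
#' @param k Trait count, >= 2.
#' @return `k * (k - 1) / 2`.
#' @export
#' @examples
#' n_pairs(63)  # 1953
n_pairs <- function(k) {
  if (any(k < 2)) stop("need at least two traits to form a pair")
  k * (k - 1) / 2
}

#' All-pairs Pearson correlation census
#'
#' Computes Pearson correlation coefficients for every unordered pair of
#' trait columns (pairwise-complete observations), with two-sided p-values
#' from the t transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 degrees of
#' freedom, and summarizes how many pairs are significant at `alpha`
#' (unadjusted). Constant columns are dropped with a warning; pairs with
#' fewer than 3 complete observations are undefined and excluded from the
#' census.
#'
#' @param traits Numeric matrix or data.frame, rows = samples, columns =
#'   traits.
#' @param alpha Significance threshold (default 0.05).
#' @return List of class `"pcc_census"`: `n_traits`, `n_pairs`, `pairs`
#'   (long data.frame: trait_a, trait_b, n, r, p), `r` and `p` matrices,
#'   `n_significant`, `percent_significant`, `alpha`, `dropped` (constant
#'   columns removed).
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
#' pcc_census(m)$pairs
pcc_census <- function(traits, alpha = 0.05) {
  m <- as.matrix(traits)
  if (!is.numeric(m)) stop("traits must be numeric")
  if (is.null(colnames(m))) colnames(m) <- paste0("trait", seq_len(ncol(m)))
  const <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2L || stats::sd(x) == 0
  })
  dropped <- colnames(m)[const]
  if (length(dropped)) {
    warning("dropping constant/degenerate trait column(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  k <- ncol(m)
  if (k < 2L) stop("need at least two non-constant traits")
  r <- stats::cor(m, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(m))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  ij <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(trait_a = colnames(m)[ij[, 1]],
                      trait_b = colnames(m)[ij[, 2]],
                      n = n[ij], r = r[ij], p = p[ij],
                      stringsAsFactors = FALSE)
  defined <- pairs$n >= 3
  if (any(!defined))
    warning(sum(!defined), " pair(s) with fewer than 3 complete observations excluded")
  pairs <- pairs[defined, , drop = FALSE]
  n_sig <- sum(pairs$p < alpha)
  structure(list(n_traits = k,
                 n_pairs = nrow(pairs),
                 pairs = pairs, r = r, p = p,
                 n_significant = n_sig,
                 percent_significant = percent_significant(n_sig, nrow(pairs)),
                 alpha = alpha,
                 dropped = dropped),
            class = "pcc_census")
}

#' @export
print.pcc_census <- function(x, ...) {
  cat(sprintf("PCC census: %d traits, %d pairs, %d significant at alpha = %g (%.2f%%)\n",
              x$n_traits, x$n_pairs, x$n_significant, x$alpha,
              x$percent_significant))
  invisible(x)
}

#' Percent of significant pairs
#'
#' @param n_significant Number of pairs with p below threshold.
#' @param n_pairs Total pairs in the census (> 0).
#' @return `100 * n_significant / n_pairs`, rounded to 2 decimals.
#' @export
#' @examples
#' percent_significant(288, 1953)  # 14.75
percent_significant <- function(n_significant, n_pairs) {
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (n_significant < 0 || n_significant > n_pairs)
    stop("n_significant must lie in [0, n_pairs]")
  round(100 * n_significant / n_pairs, 2)
}

#' One-way F comparison of |PCC| distributions across lines
#'
#' Classical one-way ANOVA F statistic on absolute correlation values
#' grouped by plant line, asking whether a trait category is more tightly
#' integrated in some lines than others.
#'
#' @param values Numeric vector (e.g. absolute Pearson correlations).
#' @param group Grouping factor of the same length, >= 2 groups with >= 2
#'   values each.
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
category_f_test <- function(values, group) {
  group <- factor(group)
  if (length(values) != length(group)) stop("values and group lengths differ")
  sizes <- table(group)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need at least two groups with at least two values each")
  a <- stats::anova(stats::lm(values ~ group))
  list(F = a[["F value"]][1],
       df_between = a[["Df"]][1],
       df_within = a[["Df"]][2],
       p = a[["Pr(>F)"]][1])
}

#' Terpenoid-carotenoid correlation by colour group
#'
#' Terpenoid volatiles and carotenoid pigments share biosynthetic
#' precursors, so a negative correlation between per-plant total terpenoid
#' emission and total carotenoids suggests a biochemical tradeoff. The
#' Pearson correlation is computed within each colour group (red vs
#' yellow), pooling species.
#'
#' @param totals Data.frame with columns `terpenoid` and `carotenoid`
#'   (per-plant totals) and `group` (colour morph).
#' @return Data.frame with one row per group: `group`, `n`, `r`, `p`.
#' @export
terpenoid_carotenoid_correlation <- function(totals) {
  need <- c("terpenoid", "carotenoid", "group")
  miss <- setdiff(need, names(totals))
  if (length(miss)) stop("totals missing columns: ", paste(miss, collapse = ", "))
  rows <- lapply(split(totals, totals$group), function(df) {
    if (nrow(df) < 3L)
      stop("group '", df$group[1], "' has fewer than 3 paired totals")
    ct <- stats::cor.test(df$terpenoid, df$carotenoid, method = "pearson")
    data.frame(group = df$group[1], n = nrow(df),
               r = unname(ct$estimate), p = unname(ct$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
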