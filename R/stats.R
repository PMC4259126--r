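#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric one-way comparison of two or more groups via the
#' rank-based H statistic with tie correction, with the p-value from the
#' chi-squared approximation on `k - 1` degrees of freedom.  When every
#' observation is identical the statistic is 0 and the p-value 1 by
#' convention (the rank distribution carries no information).
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return List with `h_statistic`, `p_value`, `df`, `n`.
#' @examples
#' kruskal_wallis(list(1:5, 6:10))  # H = 6.8182
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop("observations must be finite")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(list(h_statistic = 0, p_value = 1, df = length(groups) - 1L,
                n = length(values)))
  }
  kt <- kruskal.test(values, g)
  list(h_statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All pairwise rank-based (Wilcoxon rank-sum) comparisons between groups,
#' each declared significant when its p-value falls below
#' `alpha / C`, where `C` is the number of pairs.
#'
#' @param groups list of numeric vectors (optionally named).
#' @param alpha family-wise significance level (default 0.05).
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `p_value`, `adjusted_alpha`, `significant`.
#' @export
bonferroni_posthoc <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group_", seq_along(groups))
  pairs <- combn(length(groups), 2)
  n_pairs <- ncol(pairs)
  adj <- alpha / n_pairs
  res <- lapply(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- suppressWarnings(
      wilcox.test(groups[[i]], groups[[j]], exact = FALSE)$p.value)
    if (is.nan(p)) p <- 1  # identical constant groups
    data.frame(group_a = nm[i], group_b = nm[j], p_value = p,
               adjusted_alpha = adj, significant = p < adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# exact/enumerated permutation p-value for the two-group H statistic;
# used as an independent cross-check for small samples
kruskal_wallis_permutation <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  values <- c(x, y)
  h_of <- function(idx) {
    g <- factor(seq_len(n) %in% idx)
    r <- rank(values)
    tj <- table(r)
    tie <- 1 - sum(tj^3 - tj) / (n^3 - n)
    rs <- tapply(r, g, sum)
    ns <- tapply(r, g, length)
    h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
    h / tie
  }
  obs <- h_of(seq_len(n1))
  all_idx <- combn(n, n1)
  hs <- apply(all_idx, 2, h_of)
  list(h_statistic = obs, p_value = mean(hs >= obs - 1e-12))
}
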