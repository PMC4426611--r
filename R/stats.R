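# Exact small-sample nonparametric tests by full enumeration.
# With the handful of animals a high-pressure aquarium holds, asymptotic
# approximations are unreliable; both tests enumerate the complete null
# permutation distribution of the rank statistic whenever the arrangement
# count is tractable, and record which method produced the p-value.

new_vf_test <- function(statistic, stat_name, p_value, method, n_per_group,
                        p_fraction = NULL) {
  structure(
    list(statistic = setNames(statistic, stat_name), p_value = p_value,
         method = method, n_per_group = n_per_group, p_fraction = p_fraction),
    class = "vf_test"
  )
}

#' @export
print.vf_test <- function(x, ...) {
  cat(sprintf("%s = %.6g, p = %.6g (%s; n = %s)\n",
              names(x$statistic), x$statistic, x$p_value, x$method,
              paste(x$n_per_group, collapse = ", ")))
  if (!is.null(x$p_fraction)) {
    cat(sprintf("  exact fraction: %d / %d\n",
                x$p_fraction[["numerator"]], x$p_fraction[["denominator"]]))
  }
  invisible(x)
}

# number of distinct assignments of n items to groups of the given sizes
n_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Exact two-sample Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic from midranks and, by default, its
#' exact two-sided p-value by full enumeration of all `choose(n1+n2, n1)`
#' assignments of the observed (possibly tied) ranks to the two groups. The
#' two-sided p is `2 * min(P(U <= u), P(U >= u))`, capped at 1, and is an
#' exact rational number whose fraction is returned alongside. When the
#' arrangement count exceeds `max_enum`, a Monte-Carlo permutation p-value is
#' reported instead, with the method recorded.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param max_enum Largest arrangement count enumerated exactly (default 1e6).
#' @param n_perm Monte-Carlo permutations for the fallback (default 10000).
#' @return A `vf_test`: `statistic` (U for `x`), `p_value`, `method`
#'   (`"exact"` or `"permutation"`), `n_per_group` and, for exact mode,
#'   `p_fraction` = c(numerator, denominator).
#' @examples
#' mann_whitney_exact(c(1, 2, 4), c(3, 5, 6, 7)) # U = 1, p = 4/35
#' @export
mann_whitney_exact <- function(x, y, max_enum = 1e6, n_perm = 10000) {
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y)) # midranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  n_arr <- choose(n1 + n2, n1)
  if (n_arr <= max_enum) {
    cmb <- combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    lo <- sum(u_null <= u_obs + eps)
    hi <- sum(u_null >= u_obs - eps)
    numer <- min(2L * min(lo, hi), length(u_null))
    p <- numer / length(u_null)
    new_vf_test(u_obs, "U", p, "exact", c(n1, n2),
                p_fraction = c(numerator = as.integer(numer),
                               denominator = as.integer(length(u_null))))
  } else {
    u_null <- vapply(seq_len(n_perm), function(i) {
      sum(sample(r, n1)) - n1 * (n1 + 1) / 2
    }, numeric(1))
    lo <- (1 + sum(u_null <= u_obs + eps)) / (n_perm + 1)
    hi <- (1 + sum(u_null >= u_obs - eps)) / (n_perm + 1)
    p <- min(1, 2 * min(lo, hi))
    new_vf_test(u_obs, "U", p, "permutation", c(n1, n2))
  }
}

# tie-corrected Kruskal-Wallis H from group rank sums
kw_h_from_sums <- function(sum_sq_over_n, N, tie_correction) {
  (12 / (N * (N + 1)) * sum_sq_over_n - 3 * (N + 1)) / tie_correction
}

kw_tie_correction <- function(r) {
  t <- table(r)
  1 - sum(t^3 - t) / (length(r)^3 - length(r))
}

# enumerate sum(R_j^2 / n_j) over all distinct assignments of `ranks`
# to groups of the given sizes (last group takes the remainder)
enum_kw_sumsq <- function(ranks, sizes) {
  n <- length(ranks)
  if (length(sizes) == 1L) return(sum(ranks)^2 / sizes)
  if (length(sizes) == 2L) {
    cmb <- combn(n, sizes[[1L]])
    s1 <- colSums(matrix(ranks[cmb], nrow = sizes[[1L]]))
    tot <- sum(ranks)
    return(s1^2 / sizes[[1L]] + (tot - s1)^2 / sizes[[2L]])
  }
  cmb <- combn(n, sizes[[1L]])
  out <- vector("list", ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    pick <- cmb[, j]
    out[[j]] <- sum(ranks[pick])^2 / sizes[[1L]] +
      enum_kw_sumsq(ranks[-pick], sizes[-1L])
  }
  unlist(out, use.names = FALSE)
}

#' Exact null distribution of the Kruskal-Wallis H statistic
#'
#' Enumerates the tie-corrected H statistic over every distinct assignment of
#' the given rank multiset to groups of the given sizes. For continuous data
#' (no ties) the ranks default to `1..sum(sizes)`, so the distribution
#' depends only on the group sizes and can be computed once and reused —
#' e.g. across simulation replicates.
#'
#' @param sizes Integer group sizes (>= 2 groups).
#' @param ranks Rank multiset to permute (default `1:sum(sizes)`).
#' @return Numeric vector of H values, one per arrangement
#'   (`factorial(N) / prod(factorial(sizes))` of them).
#' @export
kw_null_distribution <- function(sizes, ranks = seq_len(sum(sizes))) {
  if (length(sizes) < 2L || any(sizes < 1L)) {
    abort("need >= 2 groups, each non-empty")
  }
  if (length(ranks) != sum(sizes)) abort("length(ranks) must equal sum(sizes)")
  N <- sum(sizes)
  tc <- kw_tie_correction(ranks)
  if (tc <= 0) abort("all observations tied; H is undefined")
  kw_h_from_sums(enum_kw_sumsq(ranks, sizes), N, tc)
}

#' Kruskal-Wallis test with exact enumeration
#'
#' Tie-corrected H statistic with a p-value from, in order of preference:
#' full enumeration of the null permutation distribution (when the number of
#' distinct group assignments is at most `max_enum`), Monte-Carlo
#' permutation, or the chi-squared approximation. The method used is
#' recorded on the result.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param method `"auto"` (default), or force `"exact"`, `"permutation"` or
#'   `"asymptotic"`.
#' @param max_enum Largest arrangement count enumerated exactly (default 3e5).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param null_h Optional precomputed [kw_null_distribution()] for these
#'   ranks and sizes, to amortize enumeration across repeated tests.
#' @return A `vf_test` with `statistic` H, `p_value`, `method`, `n_per_group`.
#' @examples
#' kruskal_wallis(list(c(1.2, 2.1, 0.8), c(3.3, 2.9, 4.1)))
#' @export
kruskal_wallis <- function(groups, method = c("auto", "exact", "permutation",
                                              "asymptotic"),
                           max_enum = 3e5, n_perm = 10000, null_h = NULL) {
  method <- match.arg(method)
  if (length(groups) < 2L) abort("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) abort("every group must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  tc <- kw_tie_correction(r)
  if (tc <= 0) {
    # every observation identical: no evidence of any difference
    return(new_vf_test(0, "H", 1, "exact", sizes))
  }
  grp <- rep(seq_along(groups), sizes)
  sumsq <- sum(tapply(r, grp, sum)^2 / sizes)
  h_obs <- kw_h_from_sums(sumsq, N, tc)
  eps <- 1e-9

  if (method == "auto") {
    method <- if (!is.null(null_h) || n_arrangements(sizes) <= max_enum) "exact"
              else "permutation"
  }
  if (method == "exact") {
    if (is.null(null_h)) {
      if (n_arrangements(sizes) > max_enum) {
        abort(sprintf(
          "exact enumeration needs %.3g arrangements (max_enum = %.3g)",
          n_arrangements(sizes), max_enum))
      }
      null_h <- kw_null_distribution(sizes, r)
    }
    p <- sum(null_h >= h_obs - eps) / length(null_h)
    new_vf_test(h_obs, "H", p, "exact", sizes)
  } else if (method == "permutation") {
    h_null <- vapply(seq_len(n_perm), function(i) {
      rp <- sample(r)
      kw_h_from_sums(sum(tapply(rp, grp, sum)^2 / sizes), N, tc)
    }, numeric(1))
    p <- (1 + sum(h_null >= h_obs - eps)) / (n_perm + 1)
    new_vf_test(h_obs, "H", p, "permutation", sizes)
  } else {
    p <- pchisq(h_obs, df = length(groups) - 1L, lower.tail = FALSE)
    new_vf_test(h_obs, "H", p, "asymptotic", sizes)
  }
}
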