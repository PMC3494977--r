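# Nonparametric rank tests, implemented from first principles.
#
# Both tests are built on midranks. The Mann-Whitney U uses the tie-corrected
# normal approximation with no continuity correction; the Wilcoxon
# signed-rank test is exact (full null distribution over all 2^n equally
# likely sign assignments) up to a configurable n, beyond which a
# tie-corrected normal approximation takes over.

#' Midranks of a numeric vector
#'
#' Ranks 1..n with tied values receiving the mean of the ranks they span,
#' so the rank sum is always n(n+1)/2.
#'
#' @param values non-empty numeric vector, all finite.
#' @return numeric vector of midranks.
#' @examples
#' rank_with_ties(c(1, 2, 2, 3))  # 1 2.5 2.5 4
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0L) kp_stop("'values' must be non-empty")
  if (!all(is.finite(values))) kp_stop("'values' must be finite")
  ord <- order(values)
  n <- length(values)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

# tie multiplicities (sizes of tie groups, including size-1 groups)
tie_group_sizes <- function(values) as.integer(table(values))

#' Tie-aware Mann-Whitney U test
#'
#' Computes \code{u1}, the number of (a, b) pairs with a > b counting ties as
#' 1/2 (via the midrank identity \code{u1 = R1 - n1(n1+1)/2}), and the
#' standardized statistic \code{z = (u_min - n1 n2 / 2) / sd(U)} using the
#' tie-corrected variance
#' \deqn{Var(U) = \frac{n_1 n_2}{12}\left[(n+1) -
#'   \frac{\sum_t (t^3 - t)}{n(n-1)}\right]}
#' over the pooled tie-group sizes t, with no continuity correction. The
#' two-sided p-value comes from the standard normal tail. When the variance
#' is zero (all pooled values tied) z = 0 and p = 1.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return object of class \code{"mann_whitney"} with fields \code{u1},
#'   \code{u2}, \code{u_min}, \code{z}, \code{p_two_sided}, \code{n1},
#'   \code{n2}, \code{tie_groups}, \code{median_a}, \code{median_b}.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5))$u_min  # 0: fully separated
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    kp_stop("both groups must be non-empty")
  if (!all(is.finite(c(group_a, group_b)))) kp_stop("values must be finite")
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank_with_ties(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u_min <- min(u1, u2)
  n <- n1 + n2
  ties <- tie_group_sizes(pooled)
  var_u <- if (n > 1)
    (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  else 0
  if (var_u > 0) {
    z <- (u_min - n1 * n2 / 2) / sqrt(var_u)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    z <- 0
    p <- 1
  }
  structure(list(u1 = u1, u2 = u2, u_min = u_min, z = z, p_two_sided = p,
                 n1 = n1, n2 = n2, tie_groups = ties,
                 median_a = stats::median(group_a),
                 median_b = stats::median(group_b)),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat("Mann-Whitney U test (tie-corrected normal approximation)\n")
  cat(sprintf("  n1 = %d, n2 = %d, medians %.4f vs %.4f\n",
              x$n1, x$n2, x$median_a, x$median_b))
  cat(sprintf("  U = %.1f (u1 = %.1f, u2 = %.1f), Z = %.4f, two-sided p = %.4g\n",
              x$u_min, x$u1, x$u2, x$z, x$p_two_sided))
  invisible(x)
}

# Exact null counts of 2*W+ given doubled midranks r2 (integers).
# Generating-function convolution over all 2^n equally likely sign vectors:
# counts[w + 1] = number of sign assignments with 2*W+ == w.
signed_rank_null_counts <- function(r2) {
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Zero differences are dropped (their count is reported); the absolute
#' values of the remaining differences are midranked; \code{w_plus} and
#' \code{w_minus} are the rank sums of positive and negative differences and
#' \code{s = min(w_plus, w_minus)}. For \code{n_used <= exact_limit} the
#' two-sided p-value is exact: over all \code{2^n} equally likely sign
#' assignments, \code{p = Pr(min(W+, W-) <= s)}. Beyond the limit a
#' tie-corrected normal approximation is used and labeled as such.
#'
#' @param differences non-empty numeric vector of paired differences.
#' @param exact_limit largest \code{n_used} for which the exact null
#'   distribution is enumerated (default 20).
#' @return object of class \code{"signed_rank"} with fields \code{w_plus},
#'   \code{w_minus}, \code{s}, \code{n_used}, \code{n_zero},
#'   \code{p_two_sided}, \code{method}.
#' @examples
#' signed_rank_exact(rep(1, 9))$p_two_sided  # 2/512 = 0.00390625
#' @export
signed_rank_exact <- function(differences, exact_limit = 20L) {
  if (length(differences) == 0L) kp_stop("'differences' must be non-empty")
  if (!all(is.finite(differences))) kp_stop("differences must be finite")
  d <- differences[differences != 0]
  n_zero <- length(differences) - length(d)
  if (length(d) == 0L) kp_stop("no informative pairs: all differences are zero")
  n <- length(d)
  r <- rank_with_ties(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  s <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))   # midranks are half-integers
    counts <- signed_rank_null_counts(r2)
    total <- sum(r2)                 # 2 * n(n+1)/2
    s2 <- round(2 * s)
    idx <- seq_along(counts) - 1L    # value of 2*W+
    hits <- sum(counts[idx <= s2 | idx >= total - s2])
    p <- min(1, hits / 2^n)
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- tie_group_sizes(abs(d))
    var_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(var_w)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(w_plus = w_plus, w_minus = w_minus, s = s,
                 n_used = n, n_zero = n_zero,
                 p_two_sided = p, method = method),
            class = "signed_rank")
}

#' @export
print.signed_rank <- function(x, ...) {
  cat("Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  if (x$n_zero > 0)
    cat(sprintf("  %d zero difference(s) dropped\n", x$n_zero))
  cat(sprintf("  n = %d, W+ = %.1f, W- = %.1f, S = %.1f, two-sided p = %.4g\n",
              x$n_used, x$w_plus, x$w_minus, x$s, x$p_two_sided))
  invisible(x)
}
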