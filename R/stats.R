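#' Mann-Whitney rank test with tie-corrected normal approximation
#'
#' Two-sample Mann-Whitney U test using midranks for ties and the normal
#' approximation with tie-corrected variance and no continuity
#' correction:
#' \deqn{Z = (U - n_1 n_2 / 2) / \sqrt{\frac{n_1 n_2}{12}\left[(n+1) -
#'   \frac{\sum (t^3 - t)}{n(n-1)}\right]}}
#' where the sum runs over tie groups of size t. The reported `zc` is
#' |Z|; `u` is the U statistic of the first sample.
#'
#' `p_two_sided` is reported from the continuity-corrected version of the
#' same approximation (|U - n1 n2/2| reduced by 1/2), the small-sample
#' calibration used by [stats::wilcox.test()]; `zc` itself stays
#' uncorrected, which is the convention behind the Z_c statistic.
#'
#' @param x,y Non-empty numeric vectors.
#' @return An object of class `rank_test`: list with `u`, `zc`,
#'   `p_two_sided`, `n1`, `n2`.
#' @examples
#' ref <- apr_reference()
#' mann_whitney_z(
#'   ref$aex_printed[ref$group == "APR"],
#'   ref$aex_printed[ref$group == "CONTROL"]
#' )
#' @export
mann_whitney_z <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("samples must be NA-free")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y)) # midranks for ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- table(c(x, y))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- if (v > 0) (u - mu) / sqrt(v) else 0
  z_cc <- if (v > 0) max(abs(u - mu) - 0.5, 0) / sqrt(v) else 0
  structure(
    list(
      u = u, zc = abs(z), p_two_sided = 2 * pnorm(-z_cc),
      n1 = n1, n2 = n2
    ),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat("<rank_test> U =", x$u, " |Z| =", round(x$zc, 3),
      " p =", signif(x$p_two_sided, 3),
      " (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  invisible(x)
}

#' Group summary: mean, SD, SE and 95 % confidence interval
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator),
#' standard error SE = SD / sqrt(n) with n the group's own size, and the
#' normal-approximation 95 % confidence interval m +/- 1.96 SE. With a
#' single observation the dispersion quantities are `NA`.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble: `n`, `m`, `sd`, `se`, `ci_low`, `ci_high`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0) abort("empty sample")
  if (anyNA(values)) abort("sample must be NA-free")
  n <- length(values)
  m <- mean(values)
  if (n == 1) {
    return(tibble(n = 1L, m = m, sd = NA_real_, se = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_))
  }
  s <- stats::sd(values)
  se <- s / sqrt(n)
  tibble(
    n = n, m = m, sd = s, se = se,
    ci_low = m - 1.96 * se, ci_high = m + 1.96 * se
  )
}

#' Toplis ratio check against overfitting
#'
#' Ratio of training-set size to the number of descriptors in the model;
#' the model passes when the ratio strictly exceeds 5:1.
#'
#' @param n_training Number of training sequences.
#' @param n_descriptors Number of descriptors (must be positive).
#' @return A list with `ratio` and `passed`.
#' @examples
#' toplis_check(84, 7)
#' @export
toplis_check <- function(n_training, n_descriptors) {
  if (n_descriptors < 1) abort("descriptor count must be positive")
  ratio <- n_training / n_descriptors
  list(ratio = ratio, passed = ratio > 5)
}
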