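#' Tidy a Cooper-statistics object
#'
#' @param x A `cooper_stats` object.
#' @param ... Unused.
#' @return A tibble with one row per statistic: `statistic`, `value`
#'   (percent).
#' @exportS3Method generics::tidy
tidy.cooper_stats <- function(x, ...) {
  stat_names <- setdiff(names(x), "counts")
  tibble(statistic = stat_names, value = unlist(x[stat_names], use.names = FALSE))
}

#' @rdname tidy.cooper_stats
#' @return For `glance()`: a one-row tibble with all nine statistics and
#'   the underlying counts.
#' @exportS3Method generics::glance
glance.cooper_stats <- function(x, ...) {
  dplyr::bind_cols(
    as_tibble(x[setdiff(names(x), "counts")]),
    tibble(tp = x$counts$tp, tn = x$counts$tn, fp = x$counts$fp,
           fn = x$counts$fn, n = x$counts$n)
  )
}

#' Tidy a rank-test result
#'
#' @param x A `rank_test` object from [mann_whitney_z()].
#' @param ... Unused.
#' @return A one-row tibble: `u`, `zc`, `p_two_sided`, `n1`, `n2`.
#' @exportS3Method generics::tidy
tidy.rank_test <- function(x, ...) {
  tibble(u = x$u, zc = x$zc, p_two_sided = x$p_two_sided,
         n1 = x$n1, n2 = x$n2)
}

#' Tidy a classified dataset
#'
#' @param x An `apr_classification` from [classify_dataset()].
#' @param ... Unused.
#' @return For `tidy()`: the per-record tibble including the assigned
#'   `class`. For `glance()`: a one-row tibble with the confusion counts
#'   and mode.
#' @exportS3Method generics::tidy
tidy.apr_classification <- function(x, ...) {
  as_tibble(x$data)
}

#' @rdname tidy.apr_classification
#' @exportS3Method generics::glance
glance.apr_classification <- function(x, ...) {
  base <- tibble(mode = x$mode, n_records = nrow(x$data))
  if (!is.null(x$confusion)) {
    c <- x$confusion
    base <- dplyr::bind_cols(base, tibble(tp = c$tp, fn = c$fn, tn = c$tn,
                                          fp = c$fp, n = c$n))
  }
  base
}
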