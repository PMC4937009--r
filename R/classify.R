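#' Quadrant class assignment on the (QPlogS, AEx) plane
#'
#' Assigns each record to one of four classes by the ordered rule set,
#' first match winning:
#' \describe{
#'   \item{A}{QPlogS > 0 and AEx < 0}
#'   \item{B}{QPlogS >= 0 and AEx > 0}
#'   \item{C}{QPlogS < 0 and AEx >= 0}
#'   \item{D}{QPlogS <= 0 and AEx <= 0 — the aggregation-prone quadrant}
#' }
#' The ordered evaluation resolves the boundary overlap at AEx = 0 with
#' QPlogS < 0 in favour of class C. The single gap in the rules
#' (QPlogS > 0 with AEx = 0) is returned as `"U"` (unclassifiable) rather
#' than guessed.
#'
#' @param qplogs,aex Numeric vectors (recycled to a common length). `aex`
#'   must be defined; an `NA` AEx is an error — callers scanning windows
#'   should skip such windows instead.
#' @return Factor with levels `A`, `B`, `C`, `D`, `U`.
#' @examples
#' assign_class(qplogs = -0.012, aex = -1.19) # class D
#' @export
assign_class <- function(qplogs, aex) {
  args <- vctrs::vec_recycle_common(qplogs = qplogs, aex = aex)
  qplogs <- args$qplogs
  aex <- args$aex
  if (anyNA(aex) || anyNA(qplogs)) {
    abort("undefined AEx/QPlogS: skip windows with undefined scores before classifying")
  }
  cls <- dplyr::case_when(
    qplogs > 0 & aex < 0 ~ "A",
    qplogs >= 0 & aex > 0 ~ "B",
    qplogs < 0 & aex >= 0 ~ "C",
    qplogs <= 0 & aex <= 0 ~ "D",
    .default = "U"
  )
  factor(cls, levels = c("A", "B", "C", "D", "U"))
}

#' Confusion counts for the APR-versus-control classifier
#'
#' @param tp,tn,fp,fn Non-negative integer counts: APR records in class D
#'   are true positives, APR elsewhere false negatives, control records in
#'   class D false positives, control elsewhere true negatives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(
    list(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp),
         fn = as.integer(fn), n = as.integer(tp + tn + fp + fn)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp =", x$tp, " fn =", x$fn, " tn =", x$tn,
      " fp =", x$fp, " (n =", x$n, ")\n")
  invisible(x)
}

#' Classify a reference-style dataset and build the confusion table
#'
#' Assigns quadrant classes to every record and tabulates per-class counts
#' by group. The confusion table contrasts APR against control records
#' only (tregitopes are excluded, matching the 84 + 42 accounting of the
#' model's validation): class D is the positive call.
#'
#' In reproduction mode (`use_printed = TRUE`, default) classes are
#' computed from the published `qplogs` and `aex_printed` columns
#' verbatim. In scoring mode descriptors are recomputed from `tables`;
#' the two modes are never mixed within one call.
#'
#' @param data A tibble with at least `sequence`, `group`, and (for
#'   reproduction mode) `qplogs` and `aex_printed`; typically
#'   [apr_reference()].
#' @param use_printed Logical; classify from printed columns (default) or
#'   recompute descriptors from `tables`.
#' @param tables,denominator Passed to [compute_descriptors()] in scoring
#'   mode.
#' @return An object of class `apr_classification`: a list with `data`
#'   (input plus `class` column), `class_counts` (tibble of group x class
#'   counts) and `confusion` (a [confusion_counts()] over APR + CONTROL).
#' @examples
#' fit <- classify_dataset(apr_reference())
#' glance(fit)
#' @export
classify_dataset <- function(data, use_printed = TRUE, tables = NULL,
                             denominator = c("distinct", "length")) {
  if (nrow(data) == 0) abort("empty dataset")
  if (use_printed) {
    if (!all(c("qplogs", "aex_printed") %in% names(data))) {
      abort("reproduction mode needs `qplogs` and `aex_printed` columns")
    }
    scored <- dplyr::mutate(data,
      class = assign_class(.data$qplogs, .data$aex_printed)
    )
  } else {
    if (is.null(tables)) abort("scoring mode needs residue `tables`")
    desc <- compute_descriptors(data$sequence, tables, match.arg(denominator))
    scored <- dplyr::bind_cols(
      dplyr::select(data, dplyr::any_of(c("id", "sequence", "group"))),
      dplyr::select(desc, -"sequence")
    )
    scored <- dplyr::filter(scored, !is.na(.data$aex))
    scored <- dplyr::mutate(scored, class = assign_class(.data$qplogs, .data$aex))
  }
  class_counts <- scored |>
    dplyr::count(.data$group, .data$class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)

  conf <- NULL
  if ("group" %in% names(scored) &&
      all(c("APR", "CONTROL") %in% as.character(scored$group))) {
    eval_set <- dplyr::filter(scored, .data$group %in% c("APR", "CONTROL"))
    is_apr <- eval_set$group == "APR"
    is_d <- eval_set$class == "D"
    conf <- confusion_counts(
      tp = sum(is_apr & is_d), fn = sum(is_apr & !is_d),
      fp = sum(!is_apr & is_d), tn = sum(!is_apr & !is_d)
    )
  }
  structure(
    list(data = scored, class_counts = class_counts, confusion = conf,
         mode = if (use_printed) "reproduce" else "score"),
    class = "apr_classification"
  )
}

#' @export
print.apr_classification <- function(x, ...) {
  cat("<apr_classification> mode:", x$mode, "\n")
  print(x$class_counts)
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}

#' Cooper validation statistics
#'
#' The nine Cooper statistics used to validate binary classification
#' models, each expressed as a percentage: sensitivity `sn`, specificity
#' `sp`, accuracy `ac`, error rate `er`, positive predictivity `pp`,
#' negative predictivity `np`, false-positive (over-classification) rate
#' `fp_oc`, false-negative (under-classification) rate `fn_uc`, and
#' `pas`, computed as Tn/(Tn + Fp). Identities `sn + fn_uc = 100`,
#' `sp + fp_oc = 100` and `ac + er = 100` hold exactly before rounding.
#' A statistic whose denominator is zero is returned as `NA`; the others
#' are still computed.
#'
#' @param x A [confusion_counts()] object or an `apr_classification`.
#' @return An object of class `cooper_stats` (named list of percentages).
#' @examples
#' cooper_statistics(confusion_counts(tp = 67, tn = 41, fp = 1, fn = 17))
#' @export
cooper_statistics <- function(x) {
  if (inherits(x, "apr_classification")) x <- x$confusion
  stopifnot(inherits(x, "confusion_counts"))
  if (x$n == 0) abort("empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(
      sn = ratio(x$tp, x$tp + x$fn),
      sp = ratio(x$tn, x$tn + x$fp),
      ac = ratio(x$tp + x$tn, x$n),
      er = ratio(x$n - (x$tp + x$tn), x$n),
      pp = ratio(x$tp, x$tp + x$fp),
      np = ratio(x$tn, x$tn + x$fn),
      fp_oc = ratio(x$fp, x$fp + x$tn),
      fn_uc = ratio(x$fn, x$fn + x$tp),
      pas = ratio(x$tn, x$tn + x$fp),
      counts = x
    ),
    class = "cooper_stats"
  )
}

#' @export
print.cooper_stats <- function(x, ...) {
  cat("<cooper_stats> (%)\n")
  v <- unlist(x[setdiff(names(x), "counts")])
  print(round(v, 2))
  invisible(x)
}

#' Sliding-window APR scan of a protein sequence
#'
#' Scores every window of `window` consecutive residues (step 1) with the
#' eight descriptors and AEx, then assigns the quadrant class. Class-D
#' windows are flagged as APR candidates. Windows whose AEx is undefined
#' (non-positive log argument) carry class `U` with a warning; windows
#' containing residues absent from the tables (e.g. ambiguity codes) are
#' skipped with a warning and reported in the `n_skipped` attribute.
#'
#' @param sequence A single protein sequence (character scalar).
#' @param tables Named list of eight residue tables; see
#'   [infer_descriptor_tables()].
#' @param window Window width in residues (default 5, the length of the
#'   reference APR peptides).
#' @param denominator Mean-rule denominator convention.
#' @param id Identifier copied into the `seq_id` column.
#' @return A tibble of class `apr_scan` with columns `seq_id`, `start`,
#'   `end` (1-based inclusive), `window`, the eight descriptors, `aex`,
#'   `class` and `apr_flag`. A sequence shorter than the window yields an
#'   empty scan with a warning.
#' @export
scan_protein <- function(sequence, tables, window = 5L,
                         denominator = c("distinct", "length"),
                         id = "protein") {
  stopifnot(length(sequence) == 1, window >= 1)
  denominator <- match.arg(denominator)
  L <- nchar(sequence)
  empty <- tibble(
    seq_id = character(), start = integer(), end = integer(),
    window = character(),
    am = numeric(), ac = numeric(), rot = numeric(), hba = numeric(),
    qpcaco = numeric(), ip = numeric(), non = numeric(), qplogs = numeric(),
    aex = numeric(), class = factor(character(), levels = c("A", "B", "C", "D", "U")),
    apr_flag = logical()
  )
  if (L < window) {
    warn(paste0("sequence '", id, "' (", L, " aa) shorter than window (",
                window, "); empty scan"))
    return(structure(empty, class = c("apr_scan", class(empty)), n_skipped = 0L))
  }
  starts <- seq_len(L - window + 1L)
  wins <- substring(sequence, starts, starts + window - 1L)
  known <- names(tables$am$values)
  scorable <- !grepl(paste0("[^", paste(known, collapse = ""), "]"), wins)
  n_skipped <- sum(!scorable)
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " window(s) of '", id,
                "' contain residues without table entries; skipped"))
  }
  idx <- which(scorable)
  if (length(idx) == 0) {
    return(structure(empty, class = c("apr_scan", class(empty)),
                     n_skipped = n_skipped))
  }
  desc <- compute_descriptors(wins[idx], tables, denominator)
  cls <- factor(rep("U", nrow(desc)), levels = c("A", "B", "C", "D", "U"))
  defined <- !is.na(desc$aex)
  cls[defined] <- assign_class(desc$qplogs[defined], desc$aex[defined])
  out <- dplyr::bind_cols(
    tibble(seq_id = id, start = starts[idx], end = starts[idx] + window - 1L),
    dplyr::rename(desc, window = "sequence")
  )
  out$class <- cls
  out$apr_flag <- cls == "D"
  structure(out, class = c("apr_scan", class(out)), n_skipped = n_skipped)
}
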