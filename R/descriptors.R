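#' Per-residue descriptor table
#'
#' A `residue_table` holds the per-residue value of one descriptor together
#' with its aggregation rule: count-like and energy-like descriptors (`am`,
#' `ac`, `rot`, `hba`, `ip`, `non`) accumulate along the chain (`"sum"`),
#' while the whole-molecule predictions `qpcaco` and `qplogs` are averaged
#' (`"mean"`).
#'
#' @param descriptor One of `"am"`, `"ac"`, `"rot"`, `"hba"`, `"qpcaco"`,
#'   `"ip"`, `"non"`, `"qplogs"`.
#' @param values Named numeric vector, one entry per one-letter residue
#'   code. Need not cover all 20 residues, but scoring a sequence that
#'   contains an uncovered residue is an error.
#' @param rule Aggregation rule; defaults to the canonical rule for
#'   `descriptor`.
#' @return An object of class `residue_table`.
#' @examples
#' unit <- residue_table("rot", setNames(rep(3, 20), aa_alphabet()))
#' sum_parameter("ALLVN", unit)
#' @export
residue_table <- function(descriptor, values,
                          rule = c("sum", "mean")[1 + (descriptor %in% c("qpcaco", "qplogs"))]) {
  descriptor <- match.arg(descriptor, names(DESCRIPTORS))
  rule <- match.arg(rule, c("sum", "mean"))
  if (is.null(names(values)) || any(names(values) == "")) {
    abort("`values` must be a named numeric vector (names are residue letters)")
  }
  bad <- setdiff(names(values), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("unknown residue letter(s) in table: ", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("`values` must be numeric and NA-free")
  }
  structure(
    list(descriptor = descriptor, rule = rule, values = unlist(values)),
    class = "residue_table"
  )
}

#' @export
print.residue_table <- function(x, ...) {
  cat("<residue_table> ", x$descriptor, " (rule: ", x$rule, ", ",
    length(x$values), " residues)\n",
    sep = ""
  )
  print(round(x$values, 4))
  invisible(x)
}

#' The canonical amino-acid alphabet
#'
#' @return Character vector of the 20 one-letter residue codes.
#' @export
aa_alphabet <- function() AA_ALPHABET

## Residue occurrence counts for one sequence; errors name the first
## offending letter and its position.
count_residues <- function(sequence, allowed = NULL) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!is.null(allowed)) {
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0) {
      abort(paste0(
        "unknown residue '", chars[bad[1]], "' at position ", bad[1],
        " of sequence '", sequence, "'"
      ))
    }
  }
  table(factor(chars, levels = unique(chars)))
}

#' Sum-rule sequence descriptor
#'
#' Aggregates a per-residue descriptor over a sequence by the sum rule:
#' the per-residue value times its occurrence count, summed over residue
#' types. The empty sequence returns 0.
#'
#' @param sequence Character vector of peptide sequences.
#' @param table A [residue_table()] with rule `"sum"`.
#' @return Numeric vector of sequence-level values.
#' @export
sum_parameter <- function(sequence, table) {
  stopifnot(inherits(table, "residue_table"))
  if (table$rule != "sum") {
    abort(paste0("descriptor ", table$descriptor, " does not use the sum rule"))
  }
  vapply(sequence, function(s) {
    if (nchar(s) == 0) return(0)
    counts <- count_residues(s, allowed = names(table$values))
    sum(table$values[names(counts)] * as.numeric(counts))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mean-rule sequence descriptor
#'
#' Aggregates a per-residue descriptor by the mean rule: the
#' occurrence-weighted sum of per-residue values divided by N, where N is
#' the number of distinct residue types in the sequence
#' (`denominator = "distinct"`, the default) or the sequence length
#' (`"length"`). The two coincide for sequences without repeated residues.
#'
#' @inheritParams sum_parameter
#' @param table A [residue_table()] with rule `"mean"`.
#' @param denominator `"distinct"` or `"length"`.
#' @return Numeric vector of sequence-level values.
#' @export
mean_parameter <- function(sequence, table, denominator = c("distinct", "length")) {
  stopifnot(inherits(table, "residue_table"))
  denominator <- match.arg(denominator)
  if (table$rule != "mean") {
    abort(paste0("descriptor ", table$descriptor, " does not use the mean rule"))
  }
  vapply(sequence, function(s) {
    if (nchar(s) == 0) abort("mean rule undefined for the empty sequence")
    counts <- count_residues(s, allowed = names(table$values))
    num <- sum(table$values[names(counts)] * as.numeric(counts))
    den <- if (denominator == "distinct") length(counts) else nchar(s)
    num / den
  }, numeric(1), USE.NAMES = FALSE)
}

#' The AEx aggregation-propensity score
#'
#' Computes `Ln(AM - IP + AC * ROT) - (QPCaco - NON)`, the arithmetic
#' expression that separates aggregation-prone regions from control
#' peptides when paired with solubility (QPlogS). `Ln` is the natural
#' logarithm. When the log argument `AM - IP + AC * ROT` is not positive
#' the score is undefined: the function warns and returns `NA`, so that
#' window scanners can skip such windows gracefully rather than fail.
#'
#' @param am,ac,rot,ip,qpcaco,non Sequence-level descriptor values
#'   (vectorized; recycled to a common length).
#' @return Numeric vector of AEx values, `NA` where undefined.
#' @examples
#' compute_aex(am = 4, ac = 4, rot = 15, ip = 39.05, qpcaco = 4.41, non = 0)
#' @export
compute_aex <- function(am, ac, rot, ip, qpcaco, non) {
  args <- vctrs::vec_recycle_common(
    am = am, ac = ac, rot = rot, ip = ip, qpcaco = qpcaco, non = non
  )
  if (!all(vapply(args, function(v) all(is.finite(v)), logical(1)))) {
    abort("all AEx inputs must be finite")
  }
  log_arg <- args$am - args$ip + args$ac * args$rot
  out <- rep(NA_real_, length(log_arg))
  ok <- log_arg > 0
  out[ok] <- log(log_arg[ok]) - (args$qpcaco[ok] - args$non[ok])
  if (any(!ok)) {
    warn(paste0(
      sum(!ok), " sequence(s) have non-positive log argument ",
      "(AM - IP + AC*ROT <= 0); AEx undefined there"
    ))
  }
  out
}

#' Compute all eight descriptors and AEx for sequences
#'
#' Applies each descriptor's aggregation rule (sum or mean) over a set of
#' per-residue tables, then evaluates the AEx score.
#'
#' @param sequence Character vector of peptide sequences.
#' @param tables Named list of eight [residue_table()]s (names `am`, `ac`,
#'   `rot`, `hba`, `qpcaco`, `ip`, `non`, `qplogs`), e.g. from
#'   [infer_descriptor_tables()].
#' @param denominator Denominator convention for the mean-rule
#'   descriptors; see [mean_parameter()].
#' @return A tibble with one row per sequence: `sequence`, the eight
#'   descriptor columns, and `aex` (`NA` where undefined).
#' @export
compute_descriptors <- function(sequence, tables, denominator = c("distinct", "length")) {
  denominator <- match.arg(denominator)
  missing <- setdiff(names(DESCRIPTORS), names(tables))
  if (length(missing) > 0) {
    abort(paste0("missing residue table(s): ", paste(missing, collapse = ", ")))
  }
  sp <- lapply(names(DESCRIPTORS), function(d) {
    tab <- tables[[d]]
    if (DESCRIPTORS[[d]] == "sum") {
      sum_parameter(sequence, tab)
    } else {
      mean_parameter(sequence, tab, denominator)
    }
  })
  names(sp) <- names(DESCRIPTORS)
  out <- tibble(sequence = sequence)
  out <- dplyr::bind_cols(out, as_tibble(sp))
  out$aex <- compute_aex(out$am, out$ac, out$rot, out$ip, out$qpcaco, out$non)
  out
}

#' Serialize residue tables to a key-value JSON document
#'
#' Writes a named list of [residue_table()]s as a flat JSON document:
#' descriptor name, aggregation rule, and the per-residue entries.
#'
#' @param tables Named list of residue tables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_tables <- function(tables, path) {
  doc <- lapply(tables, function(t) {
    list(descriptor = t$descriptor, rule = t$rule, values = as.list(t$values))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_residue_tables
#' @export
read_residue_tables <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(d) {
    residue_table(d$descriptor, unlist(d$values), rule = d$rule)
  })
}
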