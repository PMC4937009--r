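#' Residue composition matrix
#'
#' One row per sequence, one column per residue letter observed anywhere
#' in the input, entries the occurrence counts. Row sums equal sequence
#' lengths. This is the design matrix of the linear systems that recover
#' per-residue descriptor values from sequence-level ones.
#'
#' @param sequences Non-empty character vector of canonical-residue
#'   sequences.
#' @return Integer matrix with residue-letter column names.
#' @export
build_design_matrix <- function(sequences) {
  if (length(sequences) == 0) abort("no sequences supplied")
  chars <- strsplit(sequences, "", fixed = TRUE)
  bad <- which(vapply(chars, function(cc) any(!cc %in% AA_ALPHABET), logical(1)))
  if (length(bad) > 0) {
    abort(paste0("non-canonical residue in sequence '", sequences[bad[1]], "'"))
  }
  letters_seen <- sort(unique(unlist(chars)))
  m <- t(vapply(chars, function(cc) {
    tabulate(factor(cc, levels = letters_seen), nbins = length(letters_seen))
  }, integer(length(letters_seen))))
  colnames(m) <- letters_seen
  rownames(m) <- names(sequences) %||% as.character(seq_along(sequences))
  m
}

## Minimum-norm least squares via SVD, with explicit numerical rank.
## Returns the coefficient vector, rank and fitted values.
min_norm_lstsq <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  rank <- sum(pos)
  coef <- if (rank == 0) {
    rep(0, ncol(A))
  } else {
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  }
  coef <- drop(coef)
  names(coef) <- colnames(A)
  list(coef = coef, rank = rank, fitted = drop(A %*% coef))
}

new_inference_result <- function(table, residuals, rank, n_observed,
                                 denominator_mode = NA_character_,
                                 values_raw = NULL) {
  structure(
    list(
      table = table,
      residuals = residuals,
      max_abs_residual = if (length(residuals)) max(abs(residuals)) else NA_real_,
      rank = rank,
      n_observed_residues = n_observed,
      denominator_mode_selected = denominator_mode,
      values_raw = values_raw
    ),
    class = "inference_result"
  )
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result>", x$table$descriptor,
      " rank", x$rank, "/", x$n_observed_residues,
      " max|residual| =", signif(x$max_abs_residual, 4))
  if (!is.na(x$denominator_mode_selected)) {
    cat(" denominator:", x$denominator_mode_selected)
  }
  cat("\n")
  invisible(x)
}

#' Recover a sum-rule per-residue table from sequence-level values
#'
#' Solves the linear system (composition x values = sequence values) by
#' minimum-norm least squares. For the integer-valued count descriptors
#' (`am`, `ac`, `rot`, `non`) the recovered entries are rounded to the
#' nearest integer and residuals are reported for the rounded table;
#' `hba` and `ip` stay real-valued. Rank deficiency (rare or collinear
#' residues) is reported, not fatal; residues never observed get no
#' value, and scoring a sequence containing them is an error rather than
#' an extrapolation.
#'
#' @param sequences Character vector of training sequences.
#' @param sp_values Numeric vector of sequence-level descriptor values,
#'   one per sequence.
#' @param descriptor Descriptor name with the sum rule (`am`, `ac`,
#'   `rot`, `hba`, `ip`, `non`).
#' @return An `inference_result`: the fitted [residue_table()], per-
#'   sequence residuals, `max_abs_residual`, numerical `rank` and the
#'   number of observed residue letters.
#' @export
infer_sum_table <- function(sequences, sp_values, descriptor) {
  descriptor <- match.arg(descriptor, names(DESCRIPTORS)[DESCRIPTORS == "sum"])
  stopifnot(length(sequences) == length(sp_values), length(sequences) > 0)
  C <- build_design_matrix(sequences)
  fit <- min_norm_lstsq(C, sp_values)
  values <- fit$coef
  raw <- values
  if (descriptor %in% INTEGER_DESCRIPTORS) values <- round(values)
  fitted <- drop(C %*% values)
  new_inference_result(
    table = residue_table(descriptor, values, rule = "sum"),
    residuals = sp_values - fitted,
    rank = fit$rank,
    n_observed = ncol(C),
    values_raw = raw
  )
}

#' Recover a mean-rule per-residue table from sequence-level values
#'
#' The mean rule divides the occurrence-weighted sum by N; whether N is
#' the number of distinct residue types or the sequence length is decided
#' empirically: the system (composition x values = sp x N) is fitted
#' under both hypotheses and the one with the smaller residual norm is
#' selected and recorded in `denominator_mode_selected`.
#'
#' @inheritParams infer_sum_table
#' @param descriptor Descriptor name with the mean rule (`qpcaco`,
#'   `qplogs`).
#' @return An `inference_result`; residuals are on the sequence-level
#'   (mean) scale of the selected hypothesis.
#' @export
infer_mean_table <- function(sequences, sp_values, descriptor) {
  descriptor <- match.arg(descriptor, names(DESCRIPTORS)[DESCRIPTORS == "mean"])
  stopifnot(length(sequences) == length(sp_values), length(sequences) > 0)
  C <- build_design_matrix(sequences)
  n_distinct <- apply(C > 0, 1, sum)
  n_length <- rowSums(C)
  fits <- lapply(
    list(distinct = n_distinct, length = n_length),
    function(N) {
      fit <- min_norm_lstsq(C, sp_values * N)
      fit$resid_mean_scale <- sp_values - fit$fitted / N
      fit
    }
  )
  norms <- vapply(fits, function(f) sqrt(sum(f$resid_mean_scale^2)), numeric(1))
  mode <- names(which.min(norms))
  fit <- fits[[mode]]
  new_inference_result(
    table = residue_table(descriptor, fit$coef, rule = "mean"),
    residuals = fit$resid_mean_scale,
    rank = fit$rank,
    n_observed = ncol(C),
    denominator_mode = mode,
    values_raw = fit$coef
  )
}

#' Recover all eight per-residue tables from a reference table
#'
#' Fits every descriptor's per-residue table from the sequence-level
#' reference values, returning the tables ready for
#' [compute_descriptors()] and [scan_protein()], together with fit
#' diagnostics.
#'
#' @param reference A reference tibble, by default [apr_reference()].
#' @return A list with `tables` (named list of eight residue tables),
#'   `diagnostics` (tibble: descriptor, rule, rank, observed residues,
#'   max |residual|, selected denominator) and `denominator_mode` (the
#'   mode selected for `qpcaco`, used as the scanner default).
#' @examples
#' inf <- infer_descriptor_tables(apr_reference())
#' inf$diagnostics
#' @export
infer_descriptor_tables <- function(reference = apr_reference()) {
  results <- lapply(names(DESCRIPTORS), function(d) {
    if (DESCRIPTORS[[d]] == "sum") {
      infer_sum_table(reference$sequence, reference[[d]], d)
    } else {
      infer_mean_table(reference$sequence, reference[[d]], d)
    }
  })
  names(results) <- names(DESCRIPTORS)
  diagnostics <- purrr::map_dfr(results, function(r) {
    tibble(
      descriptor = r$table$descriptor,
      rule = r$table$rule,
      rank = r$rank,
      n_observed_residues = r$n_observed_residues,
      max_abs_residual = r$max_abs_residual,
      denominator_mode = r$denominator_mode_selected
    )
  })
  list(
    tables = lapply(results, `[[`, "table"),
    results = results,
    diagnostics = diagnostics,
    denominator_mode = results$qpcaco$denominator_mode_selected
  )
}
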