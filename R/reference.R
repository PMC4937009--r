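## Stored column sums of the packaged reference table, recomputed and
## compared on every load so silent fixture corruption is impossible.
REFERENCE_CHECKSUMS <- list(
  n_total = 148L,
  n_per_group = c(APR = 84L, TREGITOPE = 22L, CONTROL = 42L),
  column_sums = c(
    am = 1069, ac = 1079, rot = 4128, hba = 3709.7,
    qpcaco = 895.33, ip = 9205.11, non = 184,
    qplogs = -7.332, aex_printed = -24.63
  )
)

reference_cols <- function() {
  readr::cols(
    id = readr::col_integer(),
    sequence = readr::col_character(),
    group = readr::col_character(),
    AM = readr::col_integer(),
    AC = readr::col_integer(),
    ROT = readr::col_integer(),
    HBA = readr::col_double(),
    QPCaco = readr::col_double(),
    IP = readr::col_double(),
    NON = readr::col_integer(),
    QPlogS = readr::col_double(),
    AEx_printed = readr::col_double()
  )
}

#' Reference set of aggregation-prone regions, tregitopes and controls
#'
#' Loads the packaged reference table of 148 peptides: 84 aggregation-prone
#' regions (APR) excised from therapeutic proteins, 22 tregitope sequences,
#' and 42 control 5-mers sliced from the tregitopes. Each record carries
#' eight sequence-level physicochemical descriptors and the published AEx
#' score. The table is validated on every load; a checksum mismatch is a
#' fatal error naming the offending row or column.
#'
#' @param path Path to a reference TSV. Defaults to the packaged fixture.
#' @param validate Logical; run the full invariant and checksum validation.
#'
#' @return A tibble with columns `id`, `sequence`, `group` (factor with
#'   levels `APR`, `TREGITOPE`, `CONTROL`), the descriptors `am`, `ac`,
#'   `rot`, `hba`, `qpcaco`, `ip`, `non`, `qplogs`, and `aex_printed`.
#'
#' @details Descriptor meanings: `am` non-conjugated amine groups, `ac`
#'   carboxylic acid groups, `rot` rotatable bonds, `hba` hydrogen-bond
#'   acceptors, `qpcaco` predicted Caco-2 permeability (nm/s, sequence
#'   mean), `ip` ionization potential (eV, sequence sum), `non`
#'   non-aromatic ring atoms, `qplogs` aqueous solubility (sequence mean).
#'
#' @examples
#' ref <- apr_reference()
#' dplyr::count(ref, group)
#' @export
apr_reference <- function(path = NULL, validate = TRUE) {
  path <- path %||% system.file("extdata", "reference_table1.tsv",
    package = "aexapr", mustWork = TRUE
  )
  if (!file.exists(path)) {
    abort(paste0("reference table not found at '", path, "'"))
  }
  raw <- readr::read_tsv(path, col_types = reference_cols(), progress = FALSE)
  ref <- tibble(
    id = raw$id,
    sequence = raw$sequence,
    group = factor(raw$group, levels = c("APR", "TREGITOPE", "CONTROL")),
    am = as.numeric(raw$AM),
    ac = as.numeric(raw$AC),
    rot = as.numeric(raw$ROT),
    hba = raw$HBA,
    qpcaco = raw$QPCaco,
    ip = raw$IP,
    non = as.numeric(raw$NON),
    qplogs = raw$QPlogS,
    aex_printed = raw$AEx_printed
  )
  if (validate) validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  cs <- REFERENCE_CHECKSUMS
  if (nrow(ref) != cs$n_total) {
    abort(paste0("reference table has ", nrow(ref), " rows, expected ", cs$n_total))
  }
  counts <- table(ref$group)
  for (g in names(cs$n_per_group)) {
    if (counts[[g]] != cs$n_per_group[[g]]) {
      abort(paste0("group ", g, " has ", counts[[g]], " records, expected ",
                   cs$n_per_group[[g]]))
    }
  }
  bad_seq <- which(!grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                          ref$sequence))
  if (length(bad_seq) > 0) {
    abort(paste0("non-canonical residue in row id ", ref$id[bad_seq[1]],
                 " ('", ref$sequence[bad_seq[1]], "')"))
  }
  for (col in c("am", "ac", "rot", "non")) {
    v <- ref[[col]]
    bad <- which(v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(paste0("descriptor ", col, " not a non-negative integer in row id ",
                   ref$id[bad[1]]))
    }
  }
  for (col in names(cs$column_sums)) {
    got <- round(sum(ref[[col]]), 3)
    want <- cs$column_sums[[col]]
    if (abs(got - want) > 1e-9) {
      abort(paste0("checksum mismatch for column ", col, ": sum ", got,
                   " != stored ", want))
    }
  }
  dup <- ref[ref$id %in% c(118L, 121L), ]
  if (nrow(dup) == 2) {
    vals <- dup[, setdiff(names(dup), "id")]
    if (!identical(vals[1, ], vals[2, ])) {
      abort("rows 118 and 121 (GGLVQ) are expected to carry identical values")
    }
  }
  invisible(ref)
}

#' Write a reference table to TSV
#'
#' Serializes a reference tibble back to the packaged tab-separated layout,
#' so that a write/read round trip reproduces all records exactly.
#'
#' @param ref A tibble as returned by [apr_reference()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  out <- tibble(
    id = ref$id,
    sequence = ref$sequence,
    group = as.character(ref$group),
    AM = as.integer(ref$am),
    AC = as.integer(ref$ac),
    ROT = as.integer(ref$rot),
    HBA = sprintf("%.2f", ref$hba),
    QPCaco = sprintf("%.2f", ref$qpcaco),
    IP = sprintf("%.2f", ref$ip),
    NON = as.integer(ref$non),
    QPlogS = sprintf("%.3f", ref$qplogs),
    AEx_printed = sprintf("%.2f", ref$aex_printed)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Derive the control 5-mer set from tregitope sequences
#'
#' For each tregitope the first two non-overlapping 5-residue windows
#' (residues 1-5 and 6-10, 1-based inclusive) are extracted. The window
#' `VSWYQ`, which arises twice from distinct tregitopes, is removed in both
#' instances ("double selection"); duplicates arising from different
#' tregitopes (e.g. `GGLVQ`, `MHWVR`) are kept as separate records. Applied
#' to the 22 packaged tregitopes this yields the 42 control sequences of
#' the reference table.
#'
#' @param tregitopes Character vector of tregitope sequences, each at least
#'   10 residues long.
#' @return Character vector of control 5-mers (with duplicates retained).
#' @examples
#' derive_control_set("LMIYEVSNRPSGVPD")
#' @export
derive_control_set <- function(tregitopes) {
  if (length(tregitopes) == 0) abort("no tregitope sequences supplied")
  short <- which(nchar(tregitopes) < 10)
  if (length(short) > 0) {
    abort(paste0("tregitope '", tregitopes[short[1]],
                 "' is shorter than 10 residues"))
  }
  windows <- unlist(lapply(tregitopes, function(s) {
    c(substr(s, 1L, 5L), substr(s, 6L, 10L))
  }))
  windows[windows != "VSWYQ"]
}

#' Random peptide sequences
#'
#' Uniform random peptides over the 20-letter amino-acid alphabet,
#' reproducible for a fixed seed. Used throughout the test suite as a
#' property-test generator.
#'
#' @param n Number of peptides.
#' @param length Length of each peptide, in residues.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
random_peptides <- function(n, length, seed) {
  stopifnot(n >= 1, length >= 1)
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
    }, character(1))
  })
}
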