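test_that("sum rule aggregates occurrence-weighted per-residue values", {
  unit <- residue_table("rot", setNames(rep(1, 20), aa_alphabet()))
  expect_equal(sum_parameter("ALLVN", unit), 5)
  expect_equal(sum_parameter("", unit), 0)
  tabs <- synthetic_tables(seed = 3)
  seqs <- random_peptides(20, 8, seed = 11)
  expect_equal(
    sum_parameter(seqs, tabs$ip),
    vapply(seqs, naive_sp, numeric(1), table = tabs$ip, USE.NAMES = FALSE)
  )
  expect_error(sum_parameter("ALXVN", unit), "unknown residue 'X' at position 3")
})

test_that("mean rule divides by distinct residue count or length as asked", {
  unit <- residue_table("qpcaco", setNames(rep(1, 20), aa_alphabet()))
  # CQQYN: 5 residues, 4 distinct types
  expect_equal(mean_parameter("CQQYN", unit, "distinct"), 5 / 4)
  expect_equal(mean_parameter("CQQYN", unit, "length"), 1)
  # no repeats: the two conventions coincide
  tabs <- synthetic_tables(seed = 5)
  expect_equal(
    mean_parameter("ALMVN", tabs$qplogs, "distinct"),
    mean_parameter("ALMVN", tabs$qplogs, "length")
  )
  expect_error(mean_parameter("", unit), "empty sequence")
  expect_error(mean_parameter("ALLVN", tabs$rot), "does not use the mean rule")
})

test_that("aggregation rules are additive and permutation invariant", {
  tabs <- synthetic_tables(seed = 9)
  seqs <- random_peptides(25, 6, seed = 2)
  perms <- vapply(strsplit(seqs, ""), function(cc) {
    paste(rev(cc), collapse = "")
  }, character(1))
  expect_equal(sum_parameter(seqs, tabs$am), sum_parameter(perms, tabs$am))
  expect_equal(
    mean_parameter(seqs, tabs$qpcaco, "distinct"),
    mean_parameter(perms, tabs$qpcaco, "distinct")
  )
  s1 <- random_peptides(10, 4, seed = 21)
  s2 <- random_peptides(10, 7, seed = 22)
  expect_equal(
    sum_parameter(paste0(s1, s2), tabs$rot),
    sum_parameter(s1, tabs$rot) + sum_parameter(s2, tabs$rot)
  )
})

test_that("AEx reproduces published worked examples and boundary cases", {
  # ALLVN, reference row 1
  expect_equal(
    round(compute_aex(am = 4, ac = 4, rot = 15, ip = 39.05,
                      qpcaco = 4.41, non = 0), 2),
    -1.19
  )
  # tregitope, reference row 85
  expect_equal(
    round(compute_aex(am = 15, ac = 17, rot = 56, ip = 134.38,
                      qpcaco = 12.68, non = 8), 2),
    2.04
  )
  # log argument exactly 1, permeability cancels ring term
  expect_equal(
    compute_aex(am = 1, ac = 1, rot = 1, ip = 1, qpcaco = 2, non = 2), 0
  )
  # non-positive log argument -> NA sentinel with a warning, not an error
  expect_warning(
    out <- compute_aex(am = 0, ac = 0, rot = 0, ip = 1, qpcaco = 0, non = 0),
    "non-positive"
  )
  expect_true(is.na(out))
  expect_error(compute_aex(1, 1, Inf, 1, 1, 1), "finite")
})

test_that("AEx is monotone in permeability, ionization and ring count", {
  base <- list(am = 6, ac = 6, rot = 20, ip = 45, qpcaco = 5, non = 2)
  aex0 <- do.call(compute_aex, base)
  up <- function(field, delta) {
    args <- base
    args[[field]] <- args[[field]] + delta
    do.call(compute_aex, args)
  }
  expect_lt(up("qpcaco", 1), aex0)
  expect_lt(up("ip", 1), aex0)
  expect_gt(up("non", 1), aex0)
})

test_that("recomputing AEx from printed columns matches 147/148 rows", {
  ref <- apr_reference()
  rc <- compute_aex(ref$am, ref$ac, ref$rot, ref$ip, ref$qpcaco, ref$non)
  delta <- abs(rc - ref$aex_printed)
  expect_equal(sum(delta <= 0.02), 147)
  # the sole anomaly is the retained VVSVL control row
  expect_equal(ref$id[delta > 0.02], 129L)
  expect_equal(ref$sequence[delta > 0.02], "VVSVL")
  expect_equal(round(rc[ref$id == 129], 2), -2.46)
})

test_that("compute_descriptors is pure and matches the per-rule paths", {
  tabs <- synthetic_tables(seed = 13)
  once <- compute_descriptors("GGLVQ", tabs)
  twice <- compute_descriptors("GGLVQ", tabs)
  expect_identical(once, twice)
  expect_equal(once$rot, sum_parameter("GGLVQ", tabs$rot))
  expect_equal(once$qplogs, mean_parameter("GGLVQ", tabs$qplogs, "distinct"))
  expect_error(compute_descriptors("", tabs), "empty sequence")
  expect_error(compute_descriptors("ALLVN", tabs[-2]), "missing residue table")
})

test_that("residue tables survive a JSON round trip", {
  tabs <- synthetic_tables(seed = 17)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_residue_tables(tabs, tmp)
  back <- read_residue_tables(tmp)
  seqs <- random_peptides(5, 6, seed = 1)
  expect_equal(
    compute_descriptors(seqs, back),
    compute_descriptors(seqs, tabs)
  )
})
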