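test_that("class assignment matches published examples and the rule gap", {
  expect_equal(as.character(assign_class(-0.012, -1.19)), "D") # ALLVN
  expect_equal(as.character(assign_class(0.043, -0.63)), "A") # GGLVQ
  expect_equal(as.character(assign_class(-0.075, 0.00)), "C") # VVSVL boundary
  expect_equal(as.character(assign_class(0.5, 0.0)), "U") # rule gap
  expect_error(assign_class(0.5, NA_real_), "undefined")
})

test_that("ordered rule agrees with brute-force predicates on a sign grid", {
  grid <- expand.grid(
    qplogs = c(-1, -0.5, 0, 0.5, 1),
    aex = c(-2, -0.01, 0, 0.01, 2)
  )
  got <- as.character(assign_class(grid$qplogs, grid$aex))
  want <- mapply(predicate_class, grid$qplogs, grid$aex)
  expect_equal(got, unname(want))
})

test_that("classifying the reference reproduces published class counts", {
  fit <- classify_dataset(apr_reference())
  counts <- as.data.frame(fit$class_counts)
  apr <- counts[counts$group == "APR", c("A", "B", "C", "D")]
  cs <- counts[counts$group == "CONTROL", c("A", "B", "C", "D")]
  expect_equal(unname(unlist(apr)), c(0L, 9L, 8L, 67L))
  expect_equal(unname(unlist(cs)), c(2L, 22L, 17L, 1L))
  conf <- fit$confusion
  expect_equal(c(conf$tp, conf$fn, conf$tn, conf$fp), c(67L, 17L, 41L, 1L))
  expect_equal(conf$n, 126L)
  # per-group counts sum to group sizes
  expect_equal(rowSums(counts[, c("A", "B", "C", "D", "U")]), c(84, 22, 42),
    ignore_attr = TRUE
  )
  expect_error(classify_dataset(apr_reference()[0, ]), "empty")
})

test_that("reclassification is idempotent and order independent", {
  ref <- apr_reference()
  fit1 <- classify_dataset(ref)
  shuffled <- ref[withr::with_seed(42, sample(nrow(ref))), ]
  fit2 <- classify_dataset(shuffled)
  expect_equal(
    dplyr::arrange(tidy(fit2), id)$class,
    tidy(fit1)$class
  )
  refit <- classify_dataset(tidy(fit1))
  expect_equal(tidy(refit)$class, tidy(fit1)$class)
})

test_that("Cooper statistics reproduce the published validation block", {
  cs <- cooper_statistics(confusion_counts(tp = 67, tn = 41, fp = 1, fn = 17))
  expect_equal(round(cs$sn, 2), 79.76)
  expect_equal(round(cs$sp, 2), 97.62)
  expect_equal(round(cs$ac, 2), 85.71)
  expect_equal(round(cs$er, 2), 14.29)
  expect_equal(round(cs$pp, 2), 98.53)
  expect_equal(round(cs$np, 2), 70.69)
  expect_equal(round(cs$fp_oc, 2), 2.38)
  expect_equal(round(cs$fn_uc, 2), 20.24)
  # pas by its stated formula equals specificity, not accuracy
  expect_equal(round(cs$pas, 2), 97.62)
})

test_that("Cooper complements hold exactly and zero denominators go NA", {
  cs <- cooper_statistics(confusion_counts(tp = 67, tn = 41, fp = 1, fn = 17))
  expect_equal(cs$sn + cs$fn_uc, 100)
  expect_equal(cs$sp + cs$fp_oc, 100)
  expect_equal(cs$ac + cs$er, 100)
  perfect <- cooper_statistics(confusion_counts(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_equal(
    unlist(perfect[c("sn", "sp", "ac", "pp", "np")]),
    c(sn = 100, sp = 100, ac = 100, pp = 100, np = 100)
  )
  expect_equal(unlist(perfect[c("er", "fp_oc", "fn_uc")]),
    c(er = 0, fp_oc = 0, fn_uc = 0))
  no_neg <- cooper_statistics(confusion_counts(tp = 5, tn = 0, fp = 0, fn = 0))
  expect_true(is.na(no_neg$sp))
  expect_true(is.na(no_neg$np))
  expect_equal(no_neg$sn, 100)
  # random tables: identities and range, property style
  withr::with_seed(8, {
    for (i in 1:25) {
      k <- sample(0:30, 4, replace = TRUE)
      if (sum(k) == 0) next
      cc <- cooper_statistics(confusion_counts(k[1], k[2], k[3], k[4]))
      vals <- unlist(cc[setdiff(names(cc), "counts")])
      expect_true(all(is.na(vals) | (vals >= 0 & vals <= 100)))
      if (!is.na(cc$sn)) expect_equal(cc$sn + cc$fn_uc, 100)
      if (!is.na(cc$sp)) expect_equal(cc$sp + cc$fp_oc, 100)
    }
  })
})

test_that("sliding-window scan covers L - w + 1 windows and flags class D", {
  tabs <- infer_descriptor_tables(apr_reference())$tables
  ref <- apr_reference()
  treg85 <- ref$sequence[85]
  sc <- scan_protein(treg85, tabs, window = 5, id = "treg85")
  expect_equal(nrow(sc), nchar(treg85) - 5 + 1)
  expect_equal(sc$window[1], "LMIYE")
  expect_equal(sc$start[1], 1L)
  expect_equal(sc$end[1], 5L)
  expect_equal(sc$end - sc$start + 1L, rep(5L, nrow(sc)))
  expect_equal(sc$apr_flag, sc$class == "D")
  # degenerate input: shorter than the window
  expect_warning(empty <- scan_protein("ALLV", tabs, window = 5), "shorter")
  expect_equal(nrow(empty), 0)
  # windows holding residues without table entries are skipped, counted
  expect_warning(
    sk <- scan_protein("ALLVNXALLVN", tabs, window = 5, id = "amb"),
    "skipped"
  )
  expect_equal(attr(sk, "n_skipped"), 5L)
  expect_equal(nrow(sk), 2)
})
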