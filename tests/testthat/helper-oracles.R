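# Independent oracles and generators used across the suite. These stay
# deliberately naive (enumeration, direct predicate evaluation) so they
# never share code with the implementation they check.

# Exact two-sided Mann-Whitney p by enumeration of all choose(n1+n2, n1)
# assignments of the pooled values to the first sample.
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  u_for <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_for(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_for)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Direct, unordered-looking evaluation of the four class predicates in
# their stated order; first match wins, otherwise "U".
predicate_class <- function(qplogs, aex) {
  if (qplogs > 0 && aex < 0) return("A")
  if (qplogs >= 0 && aex > 0) return("B")
  if (qplogs < 0 && aex >= 0) return("C")
  if (qplogs <= 0 && aex <= 0) return("D")
  "U"
}

# A full synthetic set of eight residue tables with known values, for
# round-trip recovery tests. Values drawn once per seed.
synthetic_tables <- function(seed = 1) {
  withr::with_seed(seed, {
    tabs <- lapply(names(aexapr:::DESCRIPTORS), function(d) {
      vals <- if (d %in% c("am", "ac", "rot", "non")) {
        sample(0:6, 20, replace = TRUE)
      } else {
        round(runif(20, 0, 10), 3)
      }
      residue_table(d, setNames(vals, aa_alphabet()))
    })
    setNames(tabs, names(aexapr:::DESCRIPTORS))
  })
}

# Sequence-level values computed naively residue by residue (no reuse of
# sum_parameter / mean_parameter internals).
naive_sp <- function(sequence, table, denominator = "distinct") {
  chars <- strsplit(sequence, "")[[1]]
  total <- sum(table$values[chars])
  if (table$rule == "sum") {
    total
  } else {
    den <- if (denominator == "distinct") length(unique(chars)) else length(chars)
    total / den
  }
}
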