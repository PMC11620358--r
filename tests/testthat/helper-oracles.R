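# Independent oracles, written directly from first principles so they share
# no code with the implementation under test.

# Left-greedy non-overlapping C2H2 matcher built on the PCRE engine: the
# regex quantifiers are greedy and gregexpr restarts after each match end,
# which is exactly the left-greedy non-overlap rule.
oracle_scan <- function(sequence, s1 = c(2, 4), s2 = c(3, 5)) {
  if (!nzchar(sequence))
    return(data.frame(match_start = integer(), match_end = integer()))
  pat <- sprintf("C.{%d,%d}C.{3}[LIVMFYWC].{8}H.{%d,%d}H",
                 s1[1], s1[2], s2[1], s2[2])
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(match_start = integer(), match_end = integer()))
  data.frame(match_start = as.integer(m) - 1L,
             match_end = as.integer(m) - 1L + attr(m, "match.length"))
}

# Henderson-Hasselbalch net charge, residue by residue.
ORACLE_PKA <- list(pos = c(K = 10.53, R = 12.48, H = 6.0),
                   neg = c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07),
                   nterm = 9.69, cterm = 2.34)
oracle_charge <- function(peptide, pH, termini = FALSE) {
  q <- 0
  for (a in strsplit(peptide, "")[[1]]) {
    if (a %in% names(ORACLE_PKA$pos))
      q <- q + 1 / (1 + 10^(pH - ORACLE_PKA$pos[[a]]))
    if (a %in% names(ORACLE_PKA$neg))
      q <- q - 1 / (1 + 10^(ORACLE_PKA$neg[[a]] - pH))
  }
  if (termini)
    q <- q + 1 / (1 + 10^(pH - ORACLE_PKA$nterm)) -
      1 / (1 + 10^(ORACLE_PKA$cterm - pH))
  q
}

# Grid-search pI: argmin |charge| over a fine pH grid.
oracle_pi_grid <- function(peptide, step = 1e-4) {
  grid <- seq(0.1, 13.9, by = step)
  q <- vapply(grid, function(p) abs(oracle_charge(peptide, p, TRUE)),
              numeric(1))
  grid[which.min(q)]
}

# Brute-force localization score: explicit interval sums.
oracle_loc_score <- function(disome, starts, ends) {
  dom <- 0
  for (k in seq_along(starts))
    for (i in seq(starts[k] + 1, ends[k])) dom <- dom + disome[i]
  dom / sum(disome)
}

random_peptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
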