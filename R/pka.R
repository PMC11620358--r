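#' Side-chain and terminal pKa table
#'
#' Builds the dissociation-constant table used by [net_charge()] and
#' [isoelectric_point()]. The default is the Lehninger scale: Lys 10.53,
#' Arg 12.48, His 6.0, Asp 3.65, Glu 4.25, Cys 8.18, Tyr 10.07, with
#' terminal amine 9.69 and terminal carboxyl 2.34.
#'
#' @param positive named numeric vector of basic side-chain pKa values.
#' @param negative named numeric vector of acidic side-chain pKa values.
#' @param nterm,cterm terminal pKa values.
#' @param scale label for the scale the values come from.
#' @return An object of class `pka_table`.
#' @export
pka_table <- function(positive = c(K = 10.53, R = 12.48, H = 6.0),
                      negative = c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07),
                      nterm = 9.69, cterm = 2.34,
                      scale = "Lehninger") {
  all_pka <- c(positive, negative, nterm, cterm)
  if (any(all_pka <= 0 | all_pka >= 14))
    stop("all pKa values must lie in (0, 14)")
  structure(
    list(positive = positive, negative = negative,
         nterm = nterm, cterm = cterm, scale = scale),
    class = "pka_table"
  )
}

#' @export
print.pka_table <- function(x, ...) {
  cat("pKa table (", x$scale, " scale)\n", sep = "")
  cat("  basic:  ", paste(names(x$positive), x$positive, sep = "=",
                          collapse = " "), "\n")
  cat("  acidic: ", paste(names(x$negative), x$negative, sep = "=",
                          collapse = " "), "\n")
  cat("  termini: N", x$nterm, " C", x$cterm, "\n", sep = "")
  invisible(x)
}

#' Net charge of a peptide at a given pH
#'
#' Sums Henderson-Hasselbalch terms over ionizable groups: a basic group of
#' pKa k contributes +1/(1 + 10^(pH - k)), an acidic group -1/(1 + 10^(k - pH)).
#' Residues without a pKa entry contribute zero.
#'
#' @param peptide one-letter amino-acid string (non-empty).
#' @param pH solvent pH, strictly inside (0, 14).
#' @param table a [pka_table()].
#' @param include_termini count the free amino and carboxyl termini?
#' @return Net charge (numeric scalar), strictly decreasing in pH whenever
#'   the peptide carries at least one ionizable group.
#' @examples
#' net_charge("KKKKKK", pH = 7)       # ~ +6: six protonated lysines
#' net_charge("AAAAAA", pH = 7)       # exactly 0 without termini
#' @export
net_charge <- function(peptide, pH = 7.0, table = pka_table(),
                       include_termini = FALSE) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide))
    stop("peptide must be a non-empty string")
  if (!(pH > 0 && pH < 14)) stop("pH must be in (0, 14)")
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  pos_k <- table$positive[aa]
  neg_k <- table$negative[aa]
  charge <- sum(1 / (1 + 10^(pH - pos_k)), na.rm = TRUE) -
    sum(1 / (1 + 10^(neg_k - pH)), na.rm = TRUE)
  if (include_termini) {
    charge <- charge + 1 / (1 + 10^(pH - table$nterm)) -
      1 / (1 + 10^(table$cterm - pH))
  }
  charge
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the peptide's net charge (termini included) is zero.
#' The charge is monotone non-increasing in pH, so bisection on [0.1, 13.9]
#' converges unconditionally; iteration stops when |charge| < 1e-8 or the
#' bracket is narrower than 1e-10.
#'
#' @inheritParams net_charge
#' @param tol absolute charge tolerance at the returned root.
#' @return The pI (numeric scalar) with |net_charge(peptide, pI)| < `tol`.
#' @examples
#' isoelectric_point("AAAA")  # (9.69 + 2.34)/2 = 6.015, termini only
#' @export
isoelectric_point <- function(peptide, table = pka_table(), tol = 1e-4) {
  lo <- 0.1; hi <- 13.9
  f_lo <- net_charge(peptide, lo, table, include_termini = TRUE)
  f_hi <- net_charge(peptide, hi, table, include_termini = TRUE)
  if (f_lo < 0 || f_hi > 0)
    stop("charge does not bracket zero on [0.1, 13.9]")
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f_mid <- net_charge(peptide, mid, table, include_termini = TRUE)
    if (abs(f_mid) < 1e-8 || (hi - lo) < 1e-10) break
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  if (abs(f_mid) >= tol)
    stop("bisection did not reach |charge| < tol")
  mid
}
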