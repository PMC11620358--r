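# C2H2 zinc-finger detection and the 28-residue frame convention.
#
# The scanner matches the classic C2H2 consensus
#   C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H
# left-to-right with greedy spacers and no overlap between retained hits.
# Each raw match is then normalized to a fixed 28-aa frame anchored two
# residues before the first zinc-coordinating cysteine, the convention under
# which ~85% of zebrafish C2H2-ZFs are exactly 28 residues long.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PHI_SET <- c("L", "I", "V", "M", "F", "Y", "W", "C")
FRAME_LEN <- 28L

#' Scan one protein for C2H2 zinc-finger domains
#'
#' Matches the consensus pattern `C-x(s1)-C-x(3)-[LIVMFYWC]-x(8)-H-x(s2)-H`
#' where the spacer ranges `s1` (default 2-4) and `s2` (default 3-5) are
#' configurable. Matching is left-greedy: the leftmost match wins, longer
#' spacers are preferred at a given start, and scanning resumes after the
#' end of each retained match, so no two hits overlap. Raw match length is
#' always in [16 + min(s1) + min(s2), 16 + max(s1) + max(s2)] residues.
#'
#' Every hit carries a normalized 28-residue frame: `frame_start =
#' match_start - 2` clipped at 0, `frame_end = frame_start + 28` clipped at
#' the protein length, and `is_canonical_28` is TRUE only when neither end
#' was clipped.
#'
#' @param sequence one-letter amino-acid string; the 20 canonical letters
#'   plus `X` are accepted (`X` never satisfies a constrained position).
#' @param protein_id identifier carried into the result.
#' @param spacer1,spacer2 integer ranges (length-2 vectors) for the two
#'   variable spacers.
#' @return A data.frame with columns `protein_id`, `match_start`,
#'   `match_end`, `frame_start`, `frame_end`, `is_canonical_28`; coordinates
#'   are 0-based half-open, hits sorted by `match_start`. An empty sequence
#'   yields zero rows; an illegal character is an error.
#' @examples
#' scan_c2h2("CAACAAAFAAAAAAAAHAAAH")
#' @export
scan_c2h2 <- function(sequence, protein_id = "protein",
                      spacer1 = c(2L, 4L), spacer2 = c(3L, 5L)) {
  empty <- data.frame(protein_id = character(), match_start = integer(),
                      match_end = integer(), frame_start = integer(),
                      frame_end = integer(), is_canonical_28 = logical(),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("illegal residue(s) in ", protein_id, ": ",
         paste(bad, collapse = ", "))
  n <- length(aa)
  cys <- which(aa == "C")          # every match starts at a Cys
  l1s <- seq(spacer1[2L], spacer1[1L])   # greedy: longest spacer first
  l2s <- seq(spacer2[2L], spacer2[1L])
  hits <- list()
  cursor <- 1L
  for (s in cys) {
    if (s < cursor) next
    for (l1 in l1s) {
      found <- FALSE
      c2 <- s + 1L + l1                  # second Cys
      phi <- c2 + 4L                     # hydrophobic anchor after x(3)
      h1 <- phi + 9L                     # first His after x(8)
      if (h1 > n || aa[c2] != "C" || !(aa[phi] %in% PHI_SET) ||
          aa[h1] != "H") next
      for (l2 in l2s) {
        h2 <- h1 + 1L + l2
        if (h2 <= n && aa[h2] == "H") {
          hits[[length(hits) + 1L]] <- c(s - 1L, h2)  # 0-based half-open
          cursor <- h2 + 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  if (!length(hits)) return(empty)
  m <- do.call(rbind, hits)
  frame_start <- pmax(m[, 1L] - 2L, 0L)
  frame_end <- pmin(frame_start + FRAME_LEN, n)
  canonical <- (m[, 1L] >= 2L) & (m[, 1L] - 2L + FRAME_LEN <= n)
  data.frame(protein_id = protein_id,
             match_start = m[, 1L], match_end = m[, 2L],
             frame_start = frame_start, frame_end = frame_end,
             is_canonical_28 = canonical, stringsAsFactors = FALSE)
}

#' Scan a set of proteins for C2H2 zinc-finger domains
#'
#' Applies [scan_c2h2()] to each sequence. Records containing characters
#' outside the allowed alphabet are skipped with a warning and listed in the
#' `rejected` attribute of the result.
#'
#' @param proteins named character vector of sequences (names are protein
#'   IDs), or a data.frame with `protein_id` and `sequence` columns.
#' @inheritParams scan_c2h2
#' @return Row-bound hit table (see [scan_c2h2()]).
#' @export
scan_proteins <- function(proteins, spacer1 = c(2L, 4L), spacer2 = c(3L, 5L)) {
  if (is.data.frame(proteins)) {
    seqs <- proteins$sequence
    names(seqs) <- proteins$protein_id
  } else seqs <- proteins
  rejected <- character()
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- tryCatch(
      scan_c2h2(seqs[[i]], names(seqs)[i], spacer1, spacer2),
      error = function(e) {
        warning("skipping ", names(seqs)[i], ": ", conditionMessage(e),
                call. = FALSE)
        rejected <<- c(rejected, names(seqs)[i])
        NULL
      })
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- scan_c2h2("")  # canonical empty frame
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  res
}

#' Positional amino-acid frequencies over canonical 28-aa frames
#'
#' Tallies the residue observed at each of the 28 frame positions across all
#' canonical hits (the logo-matrix view of domain diversity). Zinc-coordinating
#' positions come out invariant when the input domains share them.
#'
#' @param hits hit table from [scan_c2h2()]/[scan_proteins()].
#' @param proteins named character vector of sequences keyed by protein ID.
#' @return A 28 x 20 matrix of per-position residue frequencies; every row
#'   sums to 1.
#' @export
positional_aa_frequencies <- function(hits, proteins) {
  hits <- hits[hits$is_canonical_28, , drop = FALSE]
  if (nrow(hits) == 0L) stop("no canonical 28-aa hits")
  counts <- matrix(0L, nrow = FRAME_LEN, ncol = length(AA_ALPHABET),
                   dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(nrow(hits))) {
    seq <- proteins[[hits$protein_id[i]]]
    frame <- substr(seq, hits$frame_start[i] + 1L, hits$frame_end[i])
    aa <- strsplit(frame, "", fixed = TRUE)[[1L]]
    keep <- aa %in% AA_ALPHABET
    idx <- cbind(which(keep), match(aa[keep], AA_ALPHABET))
    counts[idx] <- counts[idx] + 1L
  }
  counts / rowSums(counts)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped); the ID is the first
#'   whitespace-delimited token of each header.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_protein_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a domain hit table as TSV
#'
#' Columns `protein_id match_start match_end frame_start frame_end
#' is_canonical_28`, 0-based half-open coordinates.
#'
#' @param hits hit table.
#' @param path output file.
#' @export
write_domain_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a domain hit table written by [write_domain_table()]
#' @param path TSV file.
#' @return Hit data.frame.
#' @export
read_domain_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
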