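# Mean net charge of the nascent chain upstream of stalled (disome) A-sites,
# with a randomized-position null, and within-domain A-site histograms.
#
# Window semantics: for A-site residue index a (0-based) and offset d, the
# 6-residue window covers residues [a - d - window, a - d); windows that
# would extend before the first residue are skipped for that (a, d) pair.
# The positively charged band reported for zebrafish C2H2-ZF stalls lies
# 14-29 residues upstream of the A site, i.e. offsets ~14-23 with window 6.

#' Mean net-charge profile upstream of A-site positions
#'
#' For each offset d in `0:max_offset`, computes the mean (over contributing
#' A-sites, weighted by their read counts) of the net charge of the
#' `window`-residue peptide ending d residues before the A-site.
#'
#' @param protein_seqs named character vector of protein sequences.
#' @param asites data.frame with columns `protein_id`, `position` (0-based
#'   A-site residue index) and optionally `weight` (read count, default 1).
#' @param window window length in residues (default 6).
#' @param max_offset largest offset to report (default 40).
#' @param pH,pka passed to [net_charge()].
#' @param provenance `"observed"` or `"randomized"` label.
#' @param seed recorded seed for randomized profiles (or `NA`).
#' @return An object of class `charge_profile`: data.frame with `offset`,
#'   `mean_charge` (`NA` where no window fits), `n_windows`, plus
#'   `provenance`/`seed` attributes.
#' @export
window_charge_profile <- function(protein_seqs, asites, window = 6L,
                                  max_offset = 40L, pH = 7.0,
                                  pka = pka_table(),
                                  provenance = "observed", seed = NA) {
  if (nrow(asites) == 0L) stop("no A-site positions supplied")
  w <- if ("weight" %in% names(asites)) asites$weight else rep(1L, nrow(asites))
  offsets <- 0:max_offset
  sums <- numeric(length(offsets))
  ns <- numeric(length(offsets))
  charge_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(asites))) {
    seq <- protein_seqs[[asites$protein_id[i]]]
    a <- asites$position[i]
    for (k in seq_along(offsets)) {
      d <- offsets[k]
      lo <- a - d - window          # 0-based start
      if (lo < 0L) next
      pep <- substr(seq, lo + 1L, a - d)
      ch <- charge_cache[[pep]]
      if (is.null(ch)) {
        ch <- net_charge(pep, pH, pka)
        charge_cache[[pep]] <- ch
      }
      sums[k] <- sums[k] + w[i] * ch
      ns[k] <- ns[k] + w[i]
    }
  }
  out <- data.frame(offset = offsets,
                    mean_charge = ifelse(ns > 0, sums / ns, NA_real_),
                    n_windows = ns)
  structure(out, provenance = provenance, seed = seed,
            class = c("charge_profile", "data.frame"))
}

#' @export
print.charge_profile <- function(x, ...) {
  cat("charge_profile (", attr(x, "provenance"), "): ",
      nrow(x), " offsets, ", max(x$n_windows), " windows at peak\n", sep = "")
  NextMethod()
}

#' Randomized-position null charge profile
#'
#' Draws the same number of A-site positions uniformly (with replacement)
#' from all (canonical domain, within-domain position 0..27) pairs and
#' computes their charge profile. Deterministic for a fixed seed.
#'
#' @param domains canonical hit table ([scan_c2h2()] rows with
#'   `is_canonical_28`); non-canonical rows are dropped.
#' @param protein_seqs named character vector of sequences.
#' @param n_positions number of positions to draw (match the observed count).
#' @param seed RNG seed (mandatory, recorded in the profile).
#' @inheritParams window_charge_profile
#' @return A `charge_profile` with provenance `"randomized"`.
#' @export
randomized_charge_profile <- function(domains, protein_seqs, n_positions,
                                      seed, window = 6L, max_offset = 40L,
                                      pH = 7.0, pka = pka_table()) {
  domains <- domains[domains$is_canonical_28, , drop = FALSE]
  if (nrow(domains) == 0L) stop("no canonical domains to sample from")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  dom_idx <- sample.int(nrow(domains), n_positions, replace = TRUE)
  within <- sample.int(28L, n_positions, replace = TRUE) - 1L
  asites <- data.frame(
    protein_id = domains$protein_id[dom_idx],
    position = domains$frame_start[dom_idx] + within,
    stringsAsFactors = FALSE)
  window_charge_profile(protein_seqs, asites, window, max_offset, pH, pka,
                        provenance = "randomized", seed = seed)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract observed in-domain A-site positions from disome tracks
#'
#' Collects every disome position whose A-site falls inside a canonical
#' 28-codon frame, as (protein, residue position, weight = read count).
#'
#' @param tracks named list of [codon_track()]s.
#' @param domains canonical hit table (codon i corresponds to residue i;
#'   `protein_id` must equal the transcript ID).
#' @return data.frame `protein_id`, `position`, `weight`, `frame_position`
#'   (0..27 within-domain position).
#' @export
observed_domain_asites <- function(tracks, domains) {
  domains <- domains[domains$is_canonical_28, , drop = FALSE]
  out <- list()
  for (tr in tracks) {
    dom <- domains[domains$protein_id == tr$transcript_id, , drop = FALSE]
    if (nrow(dom) == 0L) next
    idx <- which(tr$disome > 0L) - 1L          # 0-based A-site codons
    for (i in idx) {
      k <- which(dom$frame_start <= i & i < dom$frame_end)
      if (length(k) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          protein_id = tr$transcript_id, position = i,
          weight = tr$disome[i + 1L],
          frame_position = i - dom$frame_start[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), position = integer(),
                      weight = integer(), frame_position = integer()))
  do.call(rbind, out)
}

#' Histogram of A-site positions within the 28-codon domain frame
#'
#' Counts disome A-sites (weighted by read count) at each within-domain
#' position 0..27; reads outside canonical frames are excluded.
#'
#' @param tracks named list of [codon_track()]s.
#' @param domains canonical hit table.
#' @return Integer vector of length 28 named `"0"`..`"27"`; the sum equals
#'   the number of in-frame disome reads.
#' @export
asite_histogram <- function(tracks, domains) {
  asites <- observed_domain_asites(tracks, domains)
  counts <- integer(28L)
  names(counts) <- as.character(0:27)
  if (nrow(asites)) {
    tab <- tapply(asites$weight, factor(asites$frame_position, levels = 0:27),
                  sum)
    tab[is.na(tab)] <- 0
    counts <- as.integer(tab)
    names(counts) <- as.character(0:27)
  }
  counts
}

#' Write a charge profile as TSV
#' @param profile a `charge_profile`.
#' @param path output TSV (`offset mean_charge n_windows provenance seed`).
#' @export
write_charge_profile <- function(profile, path) {
  out <- cbind(as.data.frame(profile),
               provenance = attr(profile, "provenance"),
               seed = attr(profile, "seed"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
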