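# Per-codon footprint tracks, disome occupancy and the disome localization
# score. Coordinates are 0-based half-open internally; codon i covers
# nucleotides [3i, 3i+3). Disome counts are indexed by the A-site codon of
# the leading (stalled) ribosome.

#' Per-codon footprint track for one ORF
#'
#' @param transcript_id transcript identifier.
#' @param monosome,disome non-negative integer count vectors, one entry per
#'   codon (stop codon included).
#' @param codons optional character vector of codon identities (needed only
#'   for [site_occupancy_pairs()]).
#' @return An object of class `codon_track`.
#' @export
codon_track <- function(transcript_id, monosome, disome, codons = NULL) {
  if (length(monosome) != length(disome))
    stop("monosome and disome vectors must have equal length")
  if (length(monosome) == 0L) stop("track must have at least one codon")
  if (any(monosome < 0) || any(disome < 0)) stop("counts must be >= 0")
  if (!is.null(codons) && length(codons) != length(monosome))
    stop("codons must match track length")
  structure(list(transcript_id = transcript_id,
                 n_codons = length(monosome),
                 monosome = as.integer(monosome),
                 disome = as.integer(disome),
                 codons = codons),
            class = "codon_track")
}

#' @export
print.codon_track <- function(x, ...) {
  cat("codon_track:", x$transcript_id, "-", x$n_codons, "codons,",
      sum(x$monosome), "monosome /", sum(x$disome), "disome reads\n")
  invisible(x)
}

#' C2H2-ZF codon intervals for one transcript
#'
#' Codon-coordinate domain mask (codon i corresponds to amino acid i).
#' Intervals must be sorted, non-overlapping and 0-based half-open.
#'
#' @param transcript_id transcript identifier.
#' @param starts,ends integer vectors of interval bounds, `[start, end)`.
#' @return An object of class `domain_mask`.
#' @export
domain_mask <- function(transcript_id, starts, ends) {
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (any(ends <= starts)) stop("empty or inverted interval")
  if (length(starts) > 1L) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (any(starts[-1L] < ends[-length(ends)]))
      stop("intervals overlap")
  }
  structure(list(transcript_id = transcript_id,
                 starts = as.integer(starts), ends = as.integer(ends)),
            class = "domain_mask")
}

mask_codons <- function(mask, n_codons) {
  inside <- logical(n_codons)
  for (k in seq_along(mask$starts)) {
    if (mask$ends[k] > n_codons) stop("mask interval outside ORF")
    inside[seq.int(mask$starts[k] + 1L, mask$ends[k])] <- TRUE
  }
  inside
}

#' Convert a read 5' position to its A-site codon index
#'
#' Fixed-offset A-site assignment: codon = floor((pos5 + offset)/3). Default
#' offsets are 15 nt for monosome footprints and 45 nt for the leading
#' ribosome of a disome footprint.
#'
#' @param read_5p_position 0-based nt offset of the read 5' end into the ORF.
#' @param class `"monosome"` or `"disome"`.
#' @param n_codons ORF length in codons; A-sites outside `[0, n_codons)`
#'   return `NA` (caller tallies drops).
#' @param offsets named numeric vector of per-class 5'-to-A-site offsets.
#' @return 0-based codon index, or `NA_integer_` for an out-of-ORF A-site.
#' @export
assign_asite <- function(read_5p_position, class = c("monosome", "disome"),
                         n_codons = Inf,
                         offsets = c(monosome = 15L, disome = 45L)) {
  class <- match.arg(class)
  if (any(read_5p_position < 0)) stop("negative read position")
  codon <- (read_5p_position + offsets[[class]]) %/% 3L
  codon[codon < 0L | codon >= n_codons] <- NA_integer_
  as.integer(codon)
}

#' Per-codon disome occupancy
#'
#' Occupancy is the ratio of the disome count at each codon to the mean
#' disome count per codon over the normalization region (the whole ORF, or
#' the C2H2-ZF domain codons given a mask). Mean occupancy over the region
#' is 1 by construction.
#'
#' @param track a [codon_track()].
#' @param region `"orf"` or `"domains"`.
#' @param mask a [domain_mask()], required when `region = "domains"`.
#' @return Numeric occupancy vector over all codons, or `NULL` (with a
#'   message) when the normalization region has zero reads.
#' @export
disome_occupancy <- function(track, region = c("orf", "domains"),
                             mask = NULL) {
  region <- match.arg(region)
  sel <- if (region == "orf") rep(TRUE, track$n_codons)
         else mask_codons(mask, track$n_codons)
  m <- mean(track$disome[sel])
  if (m == 0) {
    message("skipping ", track$transcript_id,
            ": zero disome reads in normalization region")
    return(NULL)
  }
  track$disome / m
}

#' Disome localization score of one transcript
#'
#' The fraction of a transcript's disome reads that fall inside its C2H2-ZF
#' domain codons: `domain_reads / total_reads`, computed over the whole ORF.
#' Transcripts with fewer than `min_reads` disome reads on the ORF are
#' reported but flagged `unscored`; a transcript without domains scores 0
#' and is flagged domain-free.
#'
#' @param track a [codon_track()].
#' @param mask a [domain_mask()] restricted to canonical 28-codon frames, or
#'   `NULL` for a domain-free transcript.
#' @param min_reads minimum disome reads on the ORF for the transcript to
#'   enter downstream analysis (default 10).
#' @return One-row data.frame: `transcript_id`, `domain_reads`,
#'   `total_reads`, `score`, `group` (initially `"unscored"` or
#'   `"scored"`), `domain_free`.
#' @export
localization_score <- function(track, mask, min_reads = 10L) {
  total <- sum(track$disome)
  if (is.null(mask) || length(mask$starts) == 0L) {
    dom <- 0L
    domain_free <- TRUE
  } else {
    dom <- sum(track$disome[mask_codons(mask, track$n_codons)])
    domain_free <- FALSE
  }
  score <- if (total > 0L) dom / total else NA_real_
  data.frame(transcript_id = track$transcript_id,
             domain_reads = dom, total_reads = total, score = score,
             group = if (total >= min_reads) "scored" else "unscored",
             domain_free = domain_free, stringsAsFactors = FALSE)
}

#' Fraction of a track's disome reads inside one codon interval
#'
#' @param track a [codon_track()].
#' @param start,end 0-based half-open codon interval within the ORF.
#' @return Fraction in `[0, 1]`; zero total reads is an error.
#' @examples
#' # 18 of 59 reads inside the interval -> 0.305
#' @export
region_read_fraction <- function(track, start, end) {
  if (start < 0 || end > track$n_codons || start > end)
    stop("interval outside ORF")
  total <- sum(track$disome)
  if (total == 0L) stop("no reads on ORF: fraction undefined")
  if (end == start) return(0)
  sum(track$disome[seq.int(start + 1L, end)]) / total
}

#' Split scored transcripts into balanced score groups
#'
#' Ranks scored transcripts by localization score (descending) and assigns
#' balanced tertiles (or `n_groups`-iles): high, middle, low. Ties are
#' broken by transcript ID in lexicographic order; group sizes differ by at
#' most one, extra members going to the higher groups.
#'
#' @param scores row-bound table from [localization_score()].
#' @param n_groups number of groups (default 3).
#' @return The table with `group` set to `"high"`, `"middle"`, `"low"` (or
#'   `"g1"`.. for other `n_groups`) for scored transcripts; unscored rows
#'   pass through unchanged.
#' @export
group_by_score <- function(scores, n_groups = 3L) {
  scored <- which(scores$group == "scored")
  if (length(scored) < n_groups)
    stop("fewer scored transcripts than groups")
  o <- scored[order(-scores$score[scored], scores$transcript_id[scored])]
  n <- length(o)
  base <- n %/% n_groups
  sizes <- rep(base, n_groups)
  extra <- n %% n_groups
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- if (n_groups == 3L) c("high", "middle", "low")
            else paste0("g", seq_len(n_groups))
  scores$group[o] <- rep(labels, times = sizes)
  scores
}

#' Simple z-score disome peak caller
#'
#' A deliberately simple stand-in peak caller (not equivalent to published
#' disome peak-calling procedures): flags codons whose disome count is at
#' least `min_count` and at least `z_threshold` standard deviations above
#' the track mean.
#'
#' @param track a [codon_track()].
#' @param z_threshold z-score cutoff.
#' @param min_count minimum raw count at a peak codon.
#' @return Integer vector of 0-based peak codon positions (possibly empty).
#' @export
call_peaks_simple <- function(track, z_threshold = 4, min_count = 5L) {
  x <- track$disome
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(integer())
  z <- (x - mean(x)) / s
  which(x >= min_count & z >= z_threshold) - 1L
}

#' Codon-level occupancy at the A-, P- and E-sites of stalled ribosomes
#'
#' For each disome position (A-site codon index i >= 2) the A-site codon is
#' `codons[i]`, the P-site codon `codons[i-1]` and the E-site codon
#' `codons[i-2]`. Occupancy vectors are computed per transcript under both
#' normalizations (whole ORF, and domain codons), and the mean occupancy per
#' sense codon per site is tabulated. Spearman's rank correlation between
#' the two normalizations is computed on the paired per-codon means,
#' excluding codons absent from either region.
#'
#' @param tracks list of [codon_track()]s carrying `codons`.
#' @param masks named list of [domain_mask()]s keyed by transcript ID.
#' @return List with `table` (codon, site, mean occupancy under each
#'   normalization) and `rho` (named numeric, one Spearman rho per site).
#' @export
site_occupancy_pairs <- function(tracks, masks) {
  stops <- c("TAA", "TAG", "TGA")
  acc <- list()  # per (codon, site, region): running sums
  add <- function(env, key, occ) {
    cur <- env[[key]]
    if (is.null(cur)) cur <- c(0, 0)
    env[[key]] <- cur + c(occ, 1)
  }
  env <- new.env(parent = emptyenv())
  for (tr in tracks) {
    if (is.null(tr$codons)) stop("track lacks codon identities")
    mask <- masks[[tr$transcript_id]]
    if (is.null(mask)) next
    occ_orf <- disome_occupancy(tr, "orf")
    occ_dom <- disome_occupancy(tr, "domains", mask)
    if (is.null(occ_orf) || is.null(occ_dom)) next
    inside <- mask_codons(mask, tr$n_codons)
    idx <- which(tr$disome > 0)
    idx <- idx[idx >= 3L]             # A-site codon index (1-based) >= 3
    for (i in idx) {
      for (site in c("A", "P", "E")) {
        j <- i - match(site, c("A", "P", "E")) + 1L
        cod <- tr$codons[j]
        if (cod %in% stops) next
        add(env, paste(cod, site, "orf", sep = "|"), occ_orf[i])
        if (inside[i])
          add(env, paste(cod, site, "dom", sep = "|"), occ_dom[i])
      }
    }
  }
  keys <- ls(env)
  if (!length(keys)) stop("no disome positions available")
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  means <- vapply(keys, function(k) env[[k]][1] / env[[k]][2], numeric(1))
  tab <- data.frame(codon = parts[, 1L], site = parts[, 2L],
                    region = parts[, 3L], mean_occupancy = unname(means),
                    stringsAsFactors = FALSE)
  rho <- sapply(c("A", "P", "E"), function(site) {
    a <- tab[tab$site == site & tab$region == "orf", ]
    b <- tab[tab$site == site & tab$region == "dom", ]
    shared <- intersect(a$codon, b$codon)
    if (length(shared) < 3L) return(NA_real_)
    stats::cor(a$mean_occupancy[match(shared, a$codon)],
               b$mean_occupancy[match(shared, b$codon)],
               method = "spearman")
  })
  list(table = tab, rho = rho)
}

#' Read sparse count tracks from TSV
#'
#' Expects columns `transcript_id codon_index monosome disome` (0-based
#' codon indices; absent codons are zero) plus a sidecar length table with
#' columns `transcript_id n_codons`.
#'
#' @param path counts TSV.
#' @param lengths_path sidecar TSV of ORF lengths in codons.
#' @return Named list of [codon_track()]s.
#' @export
read_count_tracks <- function(path, lengths_path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  tracks <- lapply(seq_len(nrow(len)), function(i) {
    id <- len$transcript_id[i]
    n <- len$n_codons[i]
    mono <- integer(n); dis <- integer(n)
    rows <- x[x$transcript_id == id, , drop = FALSE]
    mono[rows$codon_index + 1L] <- rows$monosome
    dis[rows$codon_index + 1L] <- rows$disome
    codon_track(id, mono, dis)
  })
  names(tracks) <- len$transcript_id
  tracks
}

#' Write count tracks as sparse TSV (plus length sidecar)
#'
#' @param tracks named list of [codon_track()]s.
#' @param path counts TSV to write.
#' @param lengths_path sidecar lengths TSV to write.
#' @export
write_count_tracks <- function(tracks, path, lengths_path) {
  rows <- lapply(tracks, function(tr) {
    nz <- which(tr$monosome > 0L | tr$disome > 0L)
    if (!length(nz)) return(NULL)
    data.frame(transcript_id = tr$transcript_id, codon_index = nz - 1L,
               monosome = tr$monosome[nz], disome = tr$disome[nz],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  len <- data.frame(
    transcript_id = vapply(tracks, `[[`, "", "transcript_id"),
    n_codons = vapply(tracks, `[[`, 0L, "n_codons"))
  utils::write.table(len, lengths_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
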