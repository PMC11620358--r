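# Fold-change arithmetic between genotypes/stages, maternal vs zygotic
# classification, intron-adjusted changes, gene-set fractions and
# distribution comparisons.

#' CPM-based log2 fold changes between two samples
#'
#' Counts are scaled to counts per million by the sample's library size;
#' `lfc = log2((cpmB + pc) / (cpmA + pc))`. A gene is `expressed` when its
#' CPM in the reference sample A exceeds `min_cpm`.
#'
#' @param counts gene x sample matrix (or data.frame) of non-negative
#'   counts with gene rownames.
#' @param sampleA,sampleB column names: A is the reference.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param min_cpm expression threshold in the reference sample (strict,
#'   default 1).
#' @return data.frame `gene`, `cpmA`, `cpmB`, `lfc`, `expressed`.
#' @export
cpm_log2fc <- function(counts, sampleA, sampleB, pseudocount = 0.5,
                       min_cpm = 1) {
  counts <- as.matrix(counts)
  libA <- sum(counts[, sampleA]); libB <- sum(counts[, sampleB])
  if (libA == 0 || libB == 0) stop("zero library size")
  cpmA <- 1e6 * counts[, sampleA] / libA
  cpmB <- 1e6 * counts[, sampleB] / libB
  data.frame(gene = rownames(counts), cpmA = cpmA, cpmB = cpmB,
             lfc = log2((cpmB + pseudocount) / (cpmA + pseudocount)),
             expressed = cpmA > min_cpm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maternal / zygotic / maternal-zygotic classification
#'
#' Genes whose mRNA level changes more than 2-fold from 1 hpf to 6 hpf in
#' the wild type are classed maternal (down) or zygotic (up); the rest are
#' maternal-zygotic. "More than 2-fold" is boundary-exclusive: |lfc| exactly
#' 1 is maternal-zygotic. Unexpressed genes get `NA`.
#'
#' @param records fold-change table from [cpm_log2fc()] over WT 1 hpf
#'   (reference) vs 6 hpf.
#' @return The table with an `mz_class` column.
#' @export
classify_mz <- function(records) {
  cls <- ifelse(records$lfc < -1, "maternal",
                ifelse(records$lfc > 1, "zygotic", "maternal-zygotic"))
  cls[!records$expressed] <- NA_character_
  records$mz_class <- cls
  records
}

#' Intron-adjusted log2 fold change
#'
#' Separates decay-driven from transcription-driven expression changes.
#' Intron counts are transcript-level minus exon-level counts (floored at
#' 0); the adjusted change is `lfc_mature - lfc_intron` on the log2 scale.
#' Genes whose intron CPM in the reference sample is below 1 get `NA`.
#'
#' @param transcript_counts,exon_counts gene x sample count matrices with
#'   identical dimnames.
#' @param sampleA,sampleB column names (A = reference).
#' @param pseudocount CPM pseudocount.
#' @return data.frame `gene`, `lfc_mature`, `lfc_intron`, `adjusted_lfc`,
#'   `floored` (TRUE where exon counts exceeded transcript counts).
#' @export
intron_adjusted_lfc <- function(transcript_counts, exon_counts,
                                sampleA, sampleB, pseudocount = 0.5) {
  transcript_counts <- as.matrix(transcript_counts)
  exon_counts <- as.matrix(exon_counts)
  if (!identical(dimnames(transcript_counts), dimnames(exon_counts)))
    stop("transcript and exon tables must share dimnames")
  intron <- transcript_counts - exon_counts
  floored <- intron[, sampleA] < 0 | intron[, sampleB] < 0
  intron[intron < 0] <- 0
  mature <- cpm_log2fc(exon_counts, sampleA, sampleB, pseudocount)
  if (sum(intron[, sampleA]) > 0 && sum(intron[, sampleB]) > 0) {
    pre <- cpm_log2fc(intron, sampleA, sampleB, pseudocount)
    adjusted <- mature$lfc - pre$lfc
    adjusted[pre$cpmA < 1] <- NA_real_
  } else {
    # no intronic signal at all: adjustment undefined everywhere
    pre <- data.frame(lfc = rep(NA_real_, nrow(mature)))
    adjusted <- rep(NA_real_, nrow(mature))
  }
  data.frame(gene = mature$gene, lfc_mature = mature$lfc,
             lfc_intron = pre$lfc, adjusted_lfc = adjusted,
             floored = unname(floored), stringsAsFactors = FALSE)
}

#' Percentage of a gene subset carrying a mark
#'
#' `100 * |subset intersect marked| / |subset|`, rounded to one decimal, or
#' two decimals when the subset has more than 10,000 members.
#'
#' @param subset character vector of gene IDs (must be inside `universe`).
#' @param marked character vector of marked gene IDs.
#' @param universe optional universe for the containment check.
#' @return Percentage (numeric scalar).
#' @examples
#' set_fraction(paste0("g", 1:247), paste0("g", 1:57))  # 23.1
#' @export
set_fraction <- function(subset, marked, universe = NULL) {
  if (length(subset) == 0L) stop("empty subset")
  if (!is.null(universe) && !all(subset %in% universe))
    stop("subset is not contained in universe")
  pct <- 100 * length(intersect(subset, marked)) / length(unique(subset))
  round(pct, if (length(unique(subset)) > 10000L) 2L else 1L)
}

#' Pearson chi-square test of a 2x2 enrichment table
#'
#' Pearson's chi-square without continuity correction (expected counts in
#' gene-set enrichment tables are large enough that the correction is
#' immaterial, and omitting it keeps results bit-reproducible).
#'
#' @param table2x2 2x2 matrix of non-negative integer counts with positive
#'   marginals.
#' @return List with `statistic`, `df` (1) and `p.value`.
#' @export
enrichment_chisq <- function(table2x2) {
  table2x2 <- as.matrix(table2x2)
  if (!all(dim(table2x2) == 2L)) stop("need a 2x2 table")
  if (any(rowSums(table2x2) == 0) || any(colSums(table2x2) == 0))
    stop("zero marginal")
  ht <- stats::chisq.test(table2x2, correct = FALSE)
  list(statistic = unname(ht$statistic), df = 1L,
       p.value = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison of fold-change distributions
#'
#' @param lfcA,lfcB numeric vectors (each of length >= 2).
#' @param alternative as in [stats::ks.test()]; the default two-sided test
#'   compares the two ECDFs, `"greater"`/`"less"` test directional shifts.
#' @return List with `D` and `p.value`.
#' @export
ecdf_ks <- function(lfcA, lfcB, alternative = "two.sided") {
  if (length(lfcA) < 2L || length(lfcB) < 2L)
    stop("each group needs at least 2 values")
  ht <- suppressWarnings(stats::ks.test(lfcA, lfcB,
                                        alternative = alternative))
  list(D = unname(ht$statistic), p.value = ht$p.value)
}
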