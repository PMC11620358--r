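# Seeded generators for every input the pipeline consumes, with ground
# truth for every recoverable quantity: transcriptomes carrying tandem
# canonical 28-aa C2H2-ZF arrays vs domain-free controls, Poisson footprint
# tracks with in-domain disome enrichment (optionally coupled to upstream
# nascent-chain charge), negative-binomial expression tables in which
# high-localization-score transcripts are stabilized in the mutant, and
# exponential BRIC-Seq decay courses with drifting spike-ins.

LINKER_AA <- c("A", "D", "E", "G", "K", "L", "N", "P", "Q", "R", "S", "T", "V")
# Lys/Arg-enriched linker composition: C2H2-ZF proteins have high pI
LINKER_W <- c(A = 0.10, D = 0.04, E = 0.04, G = 0.09, K = 0.18, L = 0.08,
              N = 0.05, P = 0.06, Q = 0.06, R = 0.12, S = 0.08, T = 0.06,
              V = 0.04)
PHI_PLANT <- c("L", "I", "V", "M", "F", "Y", "W")  # no Cys: keeps hits unique

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generators. The
#' defaults define the simulated study conditions: tandem arrays of 3-30
#' canonical 28-aa C2H2-ZF domains per zinc-finger transcript, background
#' footprint rate 0.2 reads/codon, 10-fold in-domain disome enrichment,
#' +0.75 log2 mutant stabilization of high-score transcripts, decay
#' courses on the 0/2/4/6/10/24 h grid with log2 noise SD 0.2 and 3
#' spike-ins.
#'
#' @param seed RNG seed (mandatory).
#' @param n_zf_transcripts,n_control_transcripts transcript counts.
#' @param domains_per_transcript inclusive range of domains per ZF
#'   transcript.
#' @param orf_length_range control-ORF length range in codons.
#' @param lambda_bg background footprint rate (reads/codon), > 0.
#' @param enrichment in-domain disome rate multiplier, > 0.
#' @param beta charge coupling: in-domain disome rate is multiplied by
#'   exp(beta * net charge of the 6-aa window 15-20 residues upstream).
#' @param delta_lfc log2 stabilization of high-score genes in the mutant
#'   at 6 hpf.
#' @param base_mean,dispersion negative-binomial expression baseline.
#' @param intron_fraction pre-mRNA (intronic) read rate relative to mature.
#' @param halflife_grid true half-lives (h) sampled for decay genes.
#' @param sigma_log2 multiplicative (log2) noise SD of decay courses.
#' @param timepoints decay sampling grid in hours (first must be 0).
#' @param n_spikeins number of spike-in rows.
#' @param spikein_sigma log2 noise SD of spike-in rows.
#' @param drift_log2_24h shared recovery drift at 24 h (log2), linear in
#'   time, that spike-in renormalization must remove.
#' @param census optional list(canonical=, total=) to plant an exact 28-aa
#'   domain-length census in [make_transcriptome()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_zf_transcripts = 50L, n_control_transcripts = 50L,
                       domains_per_transcript = c(3L, 30L),
                       orf_length_range = c(400L, 900L),
                       lambda_bg = 0.2, enrichment = 10, beta = 0,
                       delta_lfc = 0.75,
                       base_mean = 200, dispersion = 0.1,
                       intron_fraction = 0.2,
                       halflife_grid = c(2, 4, 6, 8, 12),
                       sigma_log2 = 0.2,
                       timepoints = c(0, 2, 4, 6, 10, 24),
                       n_spikeins = 3L, spikein_sigma = 0.05,
                       drift_log2_24h = 0.5,
                       census = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(lambda_bg > 0, enrichment > 0, base_mean > 0, dispersion > 0,
            timepoints[1] == 0, n_spikeins >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

sample_linker <- function(n) {
  if (n <= 0L) return(character(0))
  sample(LINKER_AA, n, replace = TRUE, prob = LINKER_W)
}

# One canonical 28-aa domain frame:
# [2 lead] C [l1] C [3] Phi [8] H [l2] H [26 - 16 - l1 - l2 trail]
plant_domain <- function(l1 = sample(2:4, 1L), l2 = sample(3:5, 1L)) {
  c(sample_linker(2L),
    "C", sample_linker(l1), "C", sample_linker(3L),
    sample(PHI_PLANT, 1L), sample_linker(8L),
    "H", sample_linker(l2), "H",
    sample_linker(10L - l1 - l2))
}

# Clipped domain variants for the length census: the raw pattern match is
# intact but the 28-aa frame runs off a protein end.
plant_domain_clipped_start <- function() {
  d <- plant_domain()
  d[-(1:2)]                       # drop the 2 lead residues: match at pos 0
}
plant_domain_clipped_end <- function(l1 = sample(2:4, 1L),
                                     l2 = sample(3:5, 1L)) {
  c(sample_linker(2L),
    "C", sample_linker(l1), "C", sample_linker(3L),
    sample(PHI_PLANT, 1L), sample_linker(8L),
    "H", sample_linker(l2), "H")  # no trailing: frame overruns the end
}

#' Generate a synthetic transcriptome with planted C2H2-ZF domains
#'
#' ZF transcripts carry tandem canonical 28-aa domains (invariant
#' zinc-coordinating Cys/His, hydrophobic anchor, Lys/Arg-enriched
#' spacers); control transcripts contain no Cys or His and therefore no
#' pattern match. With `config$census = list(canonical, total)` the
#' generator instead plants exactly `canonical` canonical and
#' `total - canonical` boundary-clipped domains so the 28-aa length census
#' is known exactly.
#'
#' @param config a [sim_config()].
#' @return List: `proteins` (named character vector), `truth` (data.frame
#'   `protein_id`, `frame_start`, `frame_end`, `is_canonical_28`), `is_zf`
#'   (named logical).
#' @export
make_transcriptome <- function(config) {
  set.seed(config$seed)
  if (!is.null(config$census)) return(make_census(config))
  proteins <- character(0)
  truth <- list()
  is_zf <- logical(0)
  for (i in seq_len(config$n_zf_transcripts)) {
    id <- sprintf("zf%03d", i)
    ndom <- sample(seq(config$domains_per_transcript[1L],
                       config$domains_per_transcript[2L]), 1L)
    parts <- list(sample_linker(sample(10:40, 1L)))
    for (d in seq_len(ndom)) {
      dom <- plant_domain()
      fs <- sum(lengths(parts))
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = id, frame_start = fs, frame_end = fs + 28L,
        is_canonical_28 = TRUE, stringsAsFactors = FALSE)
      parts <- c(parts, list(dom),
                 list(sample_linker(sample(5:30, 1L))))
    }
    proteins[id] <- paste(unlist(parts), collapse = "")
    is_zf[id] <- TRUE
  }
  for (i in seq_len(config$n_control_transcripts)) {
    id <- sprintf("ctrl%03d", i)
    len <- sample(seq(config$orf_length_range[1L],
                      config$orf_length_range[2L]), 1L)
    proteins[id] <- paste(sample_linker(len), collapse = "")
    is_zf[id] <- FALSE
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(protein_id = character(), frame_start = integer(),
               frame_end = integer(), is_canonical_28 = logical())
  list(proteins = proteins, truth = truth, is_zf = is_zf)
}

make_census <- function(config) {
  n_can <- config$census$canonical
  n_nc <- config$census$total - n_can
  n_prot <- max(1L, ceiling(n_nc / 2L))
  can_per <- diff(round(seq(0, n_can, length.out = n_prot + 1L)))
  proteins <- character(0)
  truth <- list()
  nc_left <- n_nc
  for (i in seq_len(n_prot)) {
    id <- sprintf("census%04d", i)
    parts <- list()
    if (nc_left > 0L) {           # start-clipped domain at position 0
      d <- plant_domain_clipped_start()
      # the scanner's frame for a match at position 0 is [0, 28)
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = id, frame_start = 0L, frame_end = 28L,
        is_canonical_28 = FALSE, stringsAsFactors = FALSE)
      parts <- list(d)
      nc_left <- nc_left - 1L
    } else parts <- list(sample_linker(10L))
    for (k in seq_len(can_per[i])) {
      parts <- c(parts, list(sample_linker(sample(5:15, 1L))))
      fs <- sum(lengths(parts))
      parts <- c(parts, list(plant_domain()))
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = id, frame_start = fs, frame_end = fs + 28L,
        is_canonical_28 = TRUE, stringsAsFactors = FALSE)
    }
    if (nc_left > 0L) {           # end-clipped domain at the C terminus
      parts <- c(parts, list(sample_linker(sample(5:15, 1L))))
      fs <- sum(lengths(parts))
      d <- plant_domain_clipped_end()
      parts <- c(parts, list(d))
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = id, frame_start = fs, frame_end = fs + length(d),
        is_canonical_28 = FALSE, stringsAsFactors = FALSE)
      nc_left <- nc_left - 1L
    } else parts <- c(parts, list(sample_linker(10L)))
    proteins[id] <- paste(unlist(parts), collapse = "")
  }
  truth <- do.call(rbind, truth)
  list(proteins = proteins, truth = truth,
       is_zf = stats::setNames(rep(TRUE, length(proteins)), names(proteins)))
}

aa_codon_map <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Simulate per-codon footprint tracks over a transcriptome
#'
#' Monosome counts are Poisson with rate `lambda_bg` at every codon.
#' Disome counts are Poisson with rate `lambda_bg` outside domains and
#' `lambda_bg * enrichment * exp(beta * charge)` inside, where `charge` is
#' the net charge of the 6-residue nascent-chain window 15-20 residues
#' upstream of the codon. Codon identities are sampled uniformly among
#' synonymous codons so site-level occupancy tables can be formed.
#'
#' @param transcriptome output of [make_transcriptome()].
#' @param config a [sim_config()].
#' @return List: `tracks` (named list of [codon_track()]s, stop codon
#'   appended), `masks` (named list of [domain_mask()]s for transcripts
#'   with canonical domains), `truth` (per-transcript expected
#'   localization score under the generating rates).
#' @export
simulate_footprints <- function(transcriptome, config) {
  set.seed(config$seed + 1L)
  map <- aa_codon_map()
  pka <- pka_table()
  tracks <- list()
  masks <- list()
  truth <- list()
  for (id in names(transcriptome$proteins)) {
    seq <- transcriptome$proteins[[id]]
    n_aa <- nchar(seq)
    n <- n_aa + 1L                       # stop codon included
    dom <- transcriptome$truth[
      transcriptome$truth$protein_id == id &
        transcriptome$truth$is_canonical_28, , drop = FALSE]
    inside <- logical(n)
    for (k in seq_len(nrow(dom)))
      inside[seq.int(dom$frame_start[k] + 1L, dom$frame_end[k])] <- TRUE
    rate <- rep(config$lambda_bg, n)
    if (any(inside)) {
      w <- rep(1, n)
      if (config$beta != 0) {
        for (i in which(inside)) {
          a <- i - 1L                    # 0-based residue index
          lo <- a - 14L - 6L
          if (lo >= 0L)
            w[i] <- exp(config$beta *
                          net_charge(substr(seq, lo + 1L, a - 14L),
                                     7.0, pka))
        }
      }
      rate[inside] <- config$lambda_bg * config$enrichment * w[inside]
    }
    mono <- stats::rpois(n, config$lambda_bg)
    dis <- stats::rpois(n, rate)
    aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
    codons <- c(vapply(map[aa], function(cs) cs[sample.int(length(cs), 1L)],
                       ""), "TAA")
    tracks[[id]] <- codon_track(id, mono, dis, codons = codons)
    if (nrow(dom))
      masks[[id]] <- domain_mask(id, dom$frame_start, dom$frame_end)
    truth[[id]] <- data.frame(
      transcript_id = id,
      expected_score = sum(rate[inside]) / sum(rate),
      domain_codon_fraction = mean(inside), stringsAsFactors = FALSE)
  }
  list(tracks = tracks, masks = masks, truth = do.call(rbind, truth))
}

#' Simulate two-genotype expression tables at transcript and exon level
#'
#' Negative-binomial counts for wild-type and mutant at 1 hpf and 6 hpf.
#' Exon-level counts follow mature mRNA; intronic (pre-mRNA) counts are a
#' fixed fraction of the baseline; transcript-level counts are their sum.
#' Genes labeled `high` are stabilized in the mutant at 6 hpf (mature mean
#' multiplied by `2^delta_lfc`); genes in `transcription_changed` have both
#' mature and intronic means multiplied by the same factor there, so their
#' intron-adjusted fold change vanishes.
#'
#' @param gene_groups named character vector: score group per gene
#'   (`high`/`middle`/`low`/`control`).
#' @param config a [sim_config()].
#' @param transcription_changed character vector of gene IDs given a
#'   transcription-driven (pre-mRNA-matched) change in the mutant.
#' @return List: `transcript`, `exon` (gene x sample count matrices over
#'   samples wt_1hpf, wt_6hpf, mz_1hpf, mz_6hpf), `metadata`, `truth`.
#' @export
simulate_expression <- function(gene_groups, config,
                                transcription_changed = character(0)) {
  set.seed(config$seed + 2L)
  genes <- names(gene_groups)
  ng <- length(genes)
  samples <- c("wt_1hpf", "wt_6hpf", "mz_1hpf", "mz_6hpf")
  base <- stats::rlnorm(ng, log(config$base_mean), 0.5)
  fac_stab <- 2^config$delta_lfc
  rnb <- function(mu) stats::rnbinom(ng, size = 1 / config$dispersion,
                                     mu = mu)
  exon <- matrix(0L, ng, 4L, dimnames = list(genes, samples))
  intr <- matrix(0L, ng, 4L, dimnames = list(genes, samples))
  for (s in samples) {
    mu_m <- base
    mu_i <- base * config$intron_fraction
    if (s == "mz_6hpf") {
      stab <- gene_groups == "high" & !(genes %in% transcription_changed)
      mu_m[stab] <- mu_m[stab] * fac_stab
      tc <- genes %in% transcription_changed
      mu_m[tc] <- mu_m[tc] * fac_stab
      mu_i[tc] <- mu_i[tc] * fac_stab
    }
    exon[, s] <- rnb(mu_m)
    intr[, s] <- rnb(mu_i)
  }
  metadata <- data.frame(
    sample_id = samples,
    genotype = c("WT", "WT", "MZ", "MZ"),
    stage = c("1hpf", "6hpf", "1hpf", "6hpf"), stringsAsFactors = FALSE)
  truth <- data.frame(
    gene = genes, group = unname(gene_groups),
    decay_stabilized = gene_groups == "high" &
      !(genes %in% transcription_changed),
    transcription_changed = genes %in% transcription_changed,
    stringsAsFactors = FALSE)
  list(transcript = exon + intr, exon = exon, metadata = metadata,
       truth = truth)
}

#' Simulate BRIC-Seq decay courses with spike-ins
#'
#' Gene courses follow `log2fc(t) = -t / t_half + drift(t) + noise`, with
#' true half-lives drawn from `halflife_grid`, Gaussian log2 noise of SD
#' `sigma_log2` (none at t = 0) and a shared linear recovery drift reaching
#' `drift_log2_24h` at 24 h. Spike-ins are stable RNAs carrying only the
#' drift (plus small noise), so spike-in renormalization removes the drift.
#'
#' @param n_genes number of decay genes.
#' @param config a [sim_config()].
#' @param halflives optional vector of true half-lives, recycled over
#'   genes (overrides `config$halflife_grid` sampling).
#' @return List: `courses` (table for [fit_halflives()]), `truth`
#'   (data.frame `gene`, `true_halflife`).
#' @export
simulate_bric <- function(n_genes, config, halflives = NULL) {
  set.seed(config$seed + 3L)
  tp <- config$timepoints
  hl <- if (is.null(halflives))
    sample(config$halflife_grid, n_genes, replace = TRUE)
  else rep_len(halflives, n_genes)
  drift <- config$drift_log2_24h * tp / 24
  mk_noise <- function(sigma) {
    e <- stats::rnorm(length(tp), 0, sigma); e[1L] <- 0; e
  }
  gene_y <- t(vapply(seq_len(n_genes), function(i)
    -tp / hl[i] + drift + mk_noise(config$sigma_log2),
    numeric(length(tp))))
  spike_y <- t(vapply(seq_len(config$n_spikeins), function(i)
    drift + mk_noise(config$spikein_sigma), numeric(length(tp))))
  m <- rbind(gene_y, spike_y)
  colnames(m) <- sprintf("lfc_%gh", tp)
  courses <- data.frame(
    gene = c(sprintf("gene%04d", seq_len(n_genes)),
             sprintf("spikein%d", seq_len(config$n_spikeins))),
    is_spikein = rep(c(FALSE, TRUE), c(n_genes, config$n_spikeins)),
    stringsAsFactors = FALSE)
  courses <- cbind(courses, as.data.frame(m))
  list(courses = courses,
       truth = data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                          true_halflife = hl, stringsAsFactors = FALSE))
}
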