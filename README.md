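# zfstall

Ribosome collisions on tandem C2H2 zinc-finger (C2H2-ZF) domains and
Znf598-dependent no-go mRNA decay: the analysis toolkit.

C2H2-ZF proteins are translated as long arrays of ~28-residue domains whose
lysine/arginine-rich nascent chains interact with the ribosomal exit tunnel,
stall elongation, and cause trailing ribosomes to collide with the stalled
leader. Collided ribosomes (disomes) mark the mRNA for no-go decay through
the E3 ligase Znf598. `zfstall` implements the statistics needed to test
this model on ribosome-profiling, RNA-seq and BRIC-Seq (metabolic labeling)
data, together with seeded synthetic-data generators that emit every input
with known ground truth.

## What it computes

* **C2H2-ZF scanning** — left-greedy, non-overlapping matches of
  `C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H`, normalized to a 28-aa frame
  anchored two residues before the first zinc-coordinating cysteine
  (`scan_c2h2`, `scan_proteins`, `positional_aa_frequencies`).
* **Peptide charge and pI** — Henderson–Hasselbalch net charge on the
  Lehninger pKa scale and isoelectric points by bisection (`net_charge`,
  `isoelectric_point`).
* **Disome occupancy and the disome localization score** — per-codon
  occupancy d_i / mean(d) and, per transcript, the fraction of disome reads
  falling in canonical domain codons, with the ≥10-read filter and balanced
  high/middle/low tertiles (`disome_occupancy`, `localization_score`,
  `group_by_score`, `site_occupancy_pairs`).
* **Nascent-chain charge profiles** — mean net charge of 6-aa windows
  upstream of disome A-sites, against a seeded randomized-position null
  (`window_charge_profile`, `randomized_charge_profile`,
  `asite_histogram`).
* **Expression comparisons** — CPM fold changes, maternal/zygotic
  classification (>2-fold, boundary-exclusive), intron-adjusted fold
  changes, gene-set fractions, chi-square enrichment and Kolmogorov–Smirnov
  ECDF shifts (`cpm_log2fc`, `classify_mz`, `intron_adjusted_lfc`,
  `set_fraction`, `enrichment_chisq`, `ecdf_ks`).
* **BRIC-Seq half-lives** — spike-in renormalization, nested prefix fits in
  log2 space (0–4, 0–6, 0–10, 0–24 h), max-R² selection, half-life =
  −1/slope, and the strict reliability filter R² > 0.9, 0 < t½ < 24 h
  (`spikein_renormalize`, `fit_halflife`, `fit_halflives`,
  `filter_reliable`, `halflife_fold_change`).
* **Generators** — `sim_config`, `make_transcriptome`,
  `simulate_footprints`, `simulate_expression`, `simulate_bric`.

## Worked example

Generate a 30-transcript zinc-finger transcriptome, scan it, simulate
disome footprints with 10-fold in-domain enrichment, and score the
transcripts:

```r
library(zfstall)

cfg <- sim_config(seed = 42, n_zf_transcripts = 30, n_control_transcripts = 0)
tx  <- make_transcriptome(cfg)
hits <- scan_proteins(tx$proteins)
nrow(hits)                      # 465 domains found, all canonical 28-aa
#> [1] 465

fp <- simulate_footprints(tx, cfg)
scores <- do.call(rbind, lapply(names(fp$tracks), function(id)
  localization_score(fp$tracks[[id]], fp$masks[[id]])))
scores <- group_by_score(scores)
head(scores, 3)
#>   transcript_id domain_reads total_reads     score  group domain_free
#> 1         zf001         1047        1122 0.9331551 middle       FALSE
#> 2         zf002         1639        1748 0.9376430 middle       FALSE
#> 3         zf003          334         369 0.9051491    low       FALSE
```

`score` is the disome localization score: zf001 has 1,047 of its 1,122
disome reads (93.3%) on zinc-finger codons, as expected when collisions
concentrate on the domains. Tertile grouping labels each scored transcript
high/middle/low for downstream stabilization contrasts.

Half-life estimation from a noisy decay course:

```r
f <- fit_halflife(c(0, 2, 4, 6, 10, 24), c(0, -0.48, -1.1, -1.6, -2.4, -6.1))
f
#> decay_fit: gene
#>   half-life 3.96 h (prefix 0-24 h, R2 = 0.9987, reliable)
coef(f)
#>   intercept       slope
#> -0.01019332 -0.25258348
```

The fitted slope of −0.253 log2/h halves the signal every 3.96 h; the full
0–24 h prefix maximized R², and the fit passes the reliability filter.

Charge machinery:

```r
net_charge("KRKRKR", pH = 7)    # 5.999: six fully protonated basic residues
isoelectric_point("KRKRKR")     # 12.79: strongly basic peptide
```

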