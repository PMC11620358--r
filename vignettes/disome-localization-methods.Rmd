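---
title: "Methods: disome localization on C2H2 zinc-finger domains and no-go mRNA decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disome localization on C2H2 zinc-finger domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfstall)
```

# The biological question and the computational model

Tandem C2H2 zinc-finger (C2H2-ZF) proteins — the largest transcription-factor
class in vertebrates — are translated as long arrays of ~28-residue domains
whose nascent chains are unusually rich in lysine and arginine. Positively
charged nascent peptides interact electrostatically with the negatively
charged ribosomal exit tunnel, slow elongation, and cause trailing ribosomes
to collide with the stalled leader. Collided ribosomes (disomes) are the
trigger for no-go decay (NGD): the E3 ligase Znf598 recognizes the collision
interface and routes the mRNA for degradation. `zfstall` implements the
quantitative machinery needed to test this model on ribosome-profiling,
RNA-seq and metabolic-labeling data, plus seeded generators that produce all
of those inputs with known ground truth.

The package's statistics are deliberately simple and fully specified, so
every number is reproducible bit for bit:

* **Domain detection.** C2H2-ZF domains are matched with the classic
  consensus pattern `C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H`. Matching
  is left-greedy: the leftmost match wins, longer spacers are preferred at a
  given start, and scanning resumes after each retained match, so retained
  hits never overlap and the output is order-independent. Raw matches
  (21–25 aa) are normalized to a fixed 28-aa frame anchored two residues
  before the first zinc-coordinating cysteine; a hit is *canonical* when
  neither frame end is clipped by a protein boundary. Profile-based scoring
  (position-specific matrices) would change which borderline sequences are
  detected but not any downstream arithmetic, because domains enter the
  pipeline only as coordinate masks and as a length census; the pattern
  approximation keeps the scanner transparent and exactly testable against
  an independent regular-expression oracle.

* **Disome occupancy and the localization score.** With per-codon disome
  counts indexed by the A-site of the leading (stalled) ribosome, occupancy
  at codon $i$ is $d_i / \bar d$, the count over the mean count per codon in
  the normalization region (whole ORF or domain codons), so mean occupancy
  over the region is 1 by construction. The *disome localization score* of a
  transcript is the fraction of its disome reads that fall inside canonical
  28-codon domain frames. Transcripts with fewer than 10 disome reads on the
  ORF (the score's own denominator) are reported but flagged `unscored`.
  Scored transcripts are ranked and split into balanced tertiles
  (high/middle/low); ties are broken lexicographically by transcript ID and
  group sizes differ by at most one, so the split is a deterministic
  partition regardless of the score distribution's shape.

* **Nascent-chain charge.** Net charge is the sum of Henderson–Hasselbalch
  terms: a basic group of pKa $k$ contributes $+1/(1+10^{\mathrm{pH}-k})$,
  an acidic group $-1/(1+10^{k-\mathrm{pH}})$. The pKa scale is Lehninger's
  (K 10.53, R 12.48, H 6.0, D 3.65, E 4.25, C 8.18, Y 10.07; termini
  9.69/2.34), pH 7.0 by default. The isoelectric point is the root of the
  termini-included charge, found by bisection on [0.1, 13.9] — the charge is
  monotone non-increasing in pH, so convergence is unconditional and the
  returned root satisfies $|q(\mathrm{pI})| < 10^{-4}$. Charge *profiles*
  average the charge of 6-residue windows upstream of disome A-sites: at
  offset $d$ the window covers residues $[a-d-6, a-d)$ for A-site position
  $a$; windows underflowing the N terminus are skipped, and A-sites
  contribute with their read count as multiplicity. The matched null draws
  the same number of positions uniformly *with replacement* from all
  (canonical domain, within-domain position 0–27) pairs under a recorded
  seed. The elevated-charge band reported for zebrafish C2H2-ZF stalls,
  14–29 residues upstream of the A site, corresponds to offsets ~14–23.

* **Expression comparisons.** Fold changes are plain CPM ratios with a
  pseudocount ($\mathrm{lfc} = \log_2\frac{\mathrm{cpm}_B +
  c}{\mathrm{cpm}_A + c}$, $c = 0.5$); genes above 1 CPM in the reference
  are *expressed* (strict inequality). Genes changing more than 2-fold from
  1 to 6 hpf are maternal (down) or zygotic (up), the rest maternal-zygotic
  — boundary-exclusive, so $|\mathrm{lfc}| = 1$ is maternal-zygotic.
  Intron-adjusted changes subtract the pre-mRNA (transcript-minus-exon,
  floored at zero) fold change from the mature fold change, removing
  transcription-driven components; genes with reference intron CPM below 1
  are reported `NA`. Set enrichment uses Pearson's chi-square *without*
  continuity correction (the 2×2 tables here have expected counts in the
  hundreds, where the correction is immaterial and omitting it keeps values
  exactly reproducible); distribution shifts use the two-sample
  Kolmogorov–Smirnov test on fold-change ECDFs. Percentages are printed to
  one decimal, or two when the denominator exceeds 10,000.

* **BRIC-Seq half-lives.** Per-gene log2 fold changes versus the 0 h sample
  are first renormalized by subtracting, per timepoint, the mean log2 change
  of the spike-in rows (arithmetic mean in log space = geometric mean of
  linear ratios; all fitting happens in log2 space). Because transcript
  decay often slows at late timepoints, the course is fitted by ordinary
  least squares over every *prefix* of the grid (0–4, 0–6, 0–10, 0–24 h for
  the default 0/2/4/6/10/24 h design), each prefix including the t = 0
  observation with a free intercept. The prefix with maximal $R^2$ (squared
  Pearson correlation of fitted and observed values) is selected; on ties
  the longest prefix wins (more data at equal quality — the choice matters
  only for noiseless courses, where all prefixes tie at $R^2 = 1$). On the
  log2 scale the half-life is $-1/\mathrm{slope}$ hours. A fit is *reliable*
  when $R^2 > 0.9$ and $0 < t_{1/2} < 24$ h, both bounds strict.

# What the generators emulate, and what they do not

Every generator takes a `sim_config(seed = ...)`; the same seed reproduces
byte-identical output, and every dataset ships a ground-truth table.

* `make_transcriptome()` plants tandem canonical 28-aa domains
  (3–30 per transcript, echoing the near-30-copy arrays of real FZNF genes)
  separated by Lys/Arg-enriched linkers, against domain-free controls drawn
  from an alphabet without Cys/His — so scanner recall and false-positive
  rate are exactly known. The census mode plants an exact canonical count
  (8,168 canonical of 9,622 total by default usage) using boundary-clipped
  domains for the non-canonical remainder.
* `simulate_footprints()` draws Poisson counts per codon: monosome at the
  background rate `lambda_bg` (0.2 reads/codon), disome at `lambda_bg`
  outside domains and `lambda_bg * enrichment * exp(beta * charge)` inside,
  where `charge` is the net charge of the 6-residue window 15–20 residues
  upstream. `beta > 0` produces the charge-coupled stalling the observed
  profile should detect against the randomized null.
* `simulate_expression()` draws negative-binomial counts (dispersion 0.1)
  for wild type and mutant at two stages and two counting levels
  (transcript/exon); high-score genes get their mature mean multiplied by
  $2^{\Delta\mathrm{lfc}}$ ($\Delta\mathrm{lfc} = 0.75$) in the mutant at
  6 hpf, while a labeled subset changes at both mature and pre-mRNA level to
  exercise the intron adjustment.
* `simulate_bric()` draws $\log_2\mathrm{fc}(t) = -t/t_{1/2} +
  \mathrm{drift}(t) + \varepsilon$, $\varepsilon \sim N(0, 0.2^2)$ (none at
  t = 0), with three stable spike-ins carrying the shared linear drift (0.5
  log2 at 24 h) that renormalization must remove.

The generators reproduce the *statistical structure* the analysis assumes —
count noise, in-domain enrichment, charge coupling, decay kinetics — not
real data's complications: no multi-mapping or mismatch artifacts from
near-identical paralogs, no rRNA contamination, no codon-level pause
heterogeneity beyond the charge term, no isoforms or alternative splicing,
no library-preparation biases, and expression noise is unreplicated NB
sampling rather than embryo-to-embryo variability. Passing tests therefore
demonstrate that the estimators recover what they claim from data obeying
their own assumptions; they do not validate read processing upstream of the
package's entry points.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (codon $i$ covers
  nucleotides $[3i, 3i+3)$); a single stated convention avoids off-by-one
  drift between protein, codon and interval arithmetic.
* A-site assignment from raw read positions uses one fixed configurable
  offset per footprint class (15 nt monosome, 45 nt disome leading
  ribosome); reads whose A-site leaves the ORF are dropped and tallied.
* Zero disome reads in a normalization region: the transcript is skipped
  with a diagnostic rather than producing division by zero. A zero-read ORF
  makes `region_read_fraction()` an error (0/0), while an empty interval is
  a clean 0.
* The flat decay course (zero variance) gets $R^2 = 0$ and no half-life; a
  non-negative slope yields an undefined half-life, which the reliability
  bounds then reject.
* The bisection for pI runs to a bracket of $10^{-10}$ pH units or
  $|q| < 10^{-8}$, far inside the documented $10^{-4}$ charge tolerance.
* The simple peak caller (`call_peaks_simple`, z ≥ 4 and count ≥ 5) is a
  labeled stand-in, *not* a reimplementation of published disome
  peak-calling; with zero count variance it returns no peaks.

# Known limitations

* The reliability filter ($R^2 > 0.9$, $0 < t_{1/2} < 24$ h) enriches for
  accurate estimates only when the population is heterogeneous in decay
  rate: genes with long half-lives have shallow slopes, low $R^2$ at fixed
  noise, *and* large relative error, so rejection correlates with error
  (kept median relative error 0.08 vs rejected 0.20 at noise SD 0.5 over
  the default 2–12 h grid). When every gene shares one true half-life,
  $R^2$ tracks only course noise and the filter no longer separates
  accurate from inaccurate estimates — a property worth remembering when
  interpreting filtered real-data sets of narrow rate range.
* Localization-score tertiles are balanced by rank, not by score value;
  with heavily tied scores the high/low contrast is driven by the
  tie-break, which is deterministic but arbitrary.
* The charge model treats pKa values as context-free; real nascent chains
  in the exit tunnel have shifted effective pKas, so profile *contrasts*
  (observed vs randomized) are meaningful, absolute charges less so.
* The pattern scanner requires exact Cys/His placement; genuinely divergent
  zinc fingers detectable by profile scoring are missed, which biases the
  length census toward well-formed domains.

# Problem sizes used by the shipped checks

The test suite and the reproduction script run entirely from generated
data, at sizes chosen to keep the full run in minutes on one core while
leaving the statistical claims comfortably powered: scanner-vs-oracle on
1,000 random sequences; localization-score-vs-oracle on 1,000 random
tracks; 100 random peptides for the charge oracle; a 9,622-domain census;
500 decay genes per noise condition; 150 scored transcripts (50 per
tertile) with a 199-draw Monte Carlo null for the charge-coupling and
stabilization claims.

# Session info

```{r}
sessionInfo()
```
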