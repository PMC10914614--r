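---
title: "Screening gradient proteomes for phage proteins on the host gene-expression machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gradient proteomes for phage proteins on the host gene-expression machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradsift)
```

## The measurement and the model

When a bacterial lysate is separated on a glycerol gradient, soluble
macromolecules sediment by size and density: free proteins and small
(<100 kDa) complexes stay in the first few fractions, RNA polymerase and
ribosomal subunits run deeper, polysomes deeper still, and large
aggregates or virion assembly intermediates reach the pellet at the tube
bottom. If every one of the 20 collected fractions (plus the pellet) is
quantified by mass spectrometry, each protein acquires a *sedimentation
profile* — a 21-vector of intensities — and proteins that are part of the
same particle acquire *correlated* profiles. In a phage-infected cell
this turns into a screen: a phage protein whose profile tracks the 30S or
50S ribosomal subunit is a candidate ribosome-targeting factor, long
before any structural or genetic evidence exists.

`gradsift` implements that screen as a chain of small, testable
operations:

1. **Spike-in correction.** A constant amount of a foreign protein (human
   serum albumin in the motivating experiments) is added to every
   fraction before MS. Its measured intensity `s_j` in column `j` reports
   the per-fraction technical scale, so every column is multiplied by
   `s_ref / s_j` with `s_ref = median(s_1..s_21)`. Any column-wise
   distortion applied to both the proteins and the spike-in cancels
   exactly (up to one global constant); the operation is idempotent.
2. **Profile normalization.** Fractions 1–20 are divided by their
   maximum, so the peak fraction reads 1 and the shape, not the
   abundance, is what gets compared. The pellet is expressed separately
   as its *share* of the protein's total signal,
   `P / (sum(F01..F20) + P)`, because the pellet is a qualitatively
   different compartment (aggregates, virion intermediates) and must not
   dominate a shape correlation.
3. **Abundance filter.** Proteins with `log10` total corrected intensity
   at or below 8.0 are dropped (strict `>`). Near the detection limit the
   profile shape is driven by dropout, not sedimentation, and correlation
   against it is noise.
4. **Machinery assignment.** The annotated members of each reference
   machinery (30S, 50S, RNAP, optionally another labelled complex) are
   averaged into a centroid (at least three members are required per
   label). Every profile is then assigned to the centroid with the
   highest Pearson correlation over the 20 fraction values, provided that
   correlation reaches `r_min`; otherwise it stays `"unassigned"`.
   Hierarchical clustering and a 2-D t-SNE embedding of the same vectors
   are provided for inspection, but the assignment rule is the centroid
   correlation — a figure-space cluster is suggestive, a correlation
   threshold is reproducible.
5. **Candidate calling.** A phage protein is nominated as a
   ribosome-associated factor when it (i) peaks at fraction
   `hmw_min_fraction` or deeper, (ii) is assigned to a ribosomal
   centroid, and (iii) has pellet share at most `pellet_max`. The last
   rule removes structural virion proteins, which also reach ribosomal
   depths but additionally accumulate in the pellet.
6. **Early-expression prioritization.** From an infection time course of
   transcript counts, phage transcripts are ranked by summed counts over
   the 0–10 min window; the *top set* is the minimal prefix whose
   cumulative share of phage reads strictly exceeds `cutoff`. Candidates
   whose transcripts are high in that ranking are the ones a phage needs
   immediately after injection, and they sort first.

The absolute-quantitation helpers close the loop from gels back to
molecule numbers: `ribosomes_per_cell()` is Beer–Lambert arithmetic
(`A260 / (eps * path) * volume * N_A / cells`), `cells_loaded()` scales a
CFU titre by the lane fraction, and `copies_per_cell()` divides a blot
signal by the slope of a purified-protein standard curve fitted by least
squares *through the origin* — a blot with no protein has no signal, so a
free intercept would only absorb background into the calibration.
Residuals are kept on the fitted object so a saturating (nonlinear) blot
can be rejected by inspection.

## Parameters that matter

| parameter | default | unit | why this value |
|---|---|---|---|
| `min_log10_ibaq` | 8.0 | log10 corrected intensity | conventional cut separating quantifiable profiles from dropout-dominated ones |
| `pellet_denominator` | `"total"` | — | pellet share of the protein's *total* signal; `"gradient_only"` is monotonically related and available for comparison |
| `r_min` | 0.8 | Pearson r | high enough that a 3-fraction peak offset fails; swept in the tests for monotonicity, not tuned to any dataset |
| `pellet_max` | 0.2 | share | "absent from the pellet" made quantitative; virion-like proteins in the bundled simulation sit near 0.47, ribosome-bound ones near 0.05 |
| `hmw_min_fraction` | 4 | fraction index | fractions 1–3 hold free proteins and small complexes on a 10–40% glycerol gradient |
| `cutoff` | 0.85 | cumulative share | the "most abundant transcripts exceeding 85% of phage reads" rule; strict inequality, boundary unit-tested |
| `window` | 0–10 | min | the establishment phase of infection, before late transcription dominates |

`r_min`, `pellet_max` and `hmw_min_fraction` are screening knobs, not
fitted constants: the candidate set is provably monotone in each (tested
over grids), so tightening them can only shrink the list.

## What the synthetic data emulate — and what they do not

Real deposited gradient proteomes are large and carry no ground truth, so
the package ships a generator whose *truth labels* make every stage
falsifiable. `simulate_gradient()` draws, for each protein class, a
Gaussian sedimentation shape on the fraction index (renormalized over
fractions 1–20), an optional free-pool at fraction 2 (weight 0.1), a
class-specific pellet mass, per-protein abundance from a class-specific
log-uniform band, multiplicative lognormal MS noise (CV 0.2), a hard
detection limit at 0.1% of the median underlying signal, and a
per-fraction lognormal technical scale factor (sdlog 0.3) that also
multiplies the constant spike-in row. The default layout places free
proteins at fraction 2, an RNAP-like class at 5, 30S at 11, 50S at 14 and
a 70S/polysome class at 17, with 40 phage proteins including 8 planted
ribosome binders and 6 pellet-heavy virion proteins (~440 proteins
total). Complexed classes draw from a higher abundance band than free
proteins — the gene-expression machinery carries a large share of
cellular protein mass, which is also what makes the log10 > 8 filter a
sensible screen in real data.

Two modelling choices deserve a note. The pellet is generated as its own
compartment rather than as a 21st point of the Gaussian, mirroring its
separate normalization. And the detection limit is applied to the
*underlying* signal (before the per-fraction scale factor), so the
dropout pattern is a property of the protein, not of the technical
distortion; this is what lets the spike-in correction invert a column
distortion exactly, which the tests assert to 1e-10.

`simulate_timecourse()` gives each phage transcript class a logistic
accumulation `a_i * plogis((t - tau_class) / s_class)` with onsets 2, 3,
6 and 9 min for early-ribosome, early-other, mid-nvRNAP and
late-structural classes; host transcripts are flat until 2 min and then
decay linearly at 2.5%/min (host takeover). Early classes carry larger
amplitude multipliers, reflecting that ribosome-fraction transcripts are
among the most abundant early mRNAs. The total phage amplitude is
calibrated *analytically* inside the config so that the expected phage
CDS share at 10 min equals `target_share` (default 0.40) before Poisson
sampling — the generator is built to the stated study conditions, not
adjusted afterwards. Counts are Poisson draws; each transcript (and each
protein in the gradient) has a seed derived from the global seed, so
outputs are reproducible row-by-row and independent of row order.

What the simulation does **not** reproduce: multi-modal real profiles
beyond a single free+complex mixture, correlated (batch-like) noise
between neighbouring fractions, compositional coupling between proteins
competing for MS signal, rRNA-depletion artefacts, transcript-length
effects on counts, and any physical (Svedberg) mapping from particle mass
to fraction index. Passing the recovery tests therefore shows that the
*inference chain is correct under its stated model*, not that the model
captures everything a real gradient does.

## Numerical choices

* **Correlation distance.** `1 - Pearson r` over fractions 1–20 only;
  values are clamped at 0 from below to absorb floating-point noise on
  perfectly correlated pairs. Zero-variance profiles are an error, never
  silently NA.
* **Deterministic agglomeration.** Clustering uses Lance–Williams
  updates with a fixed convention: a cluster is identified by its
  smallest original row index, and ties in the minimal linkage break to
  the lexicographically smallest index pair. The test suite replays the
  merge sequence against an exhaustive re-computation from scratch on
  small instances, and checks partition agreement with `stats::hclust`
  on tie-free data.
* **Peak ties** break to the lowest fraction index (`which.max`).
* **All-pellet rows** (zero in fractions 1–20, positive pellet) get
  all-zero fractions, pellet share 1 and `NA` peak; all-zero rows are an
  error upstream.
* **Subunit ties** in `classify_subunit()` (|Δr| < 1e-9) are signalled as
  an ambiguous-class warning and returned as `NA` — a 30S/50S call that
  close is a manual-review case, not a coin flip.
* **t-SNE** is the exact O(n²) formulation (perplexity by per-point
  binary search, early exaggeration, adaptive gains), seeded and
  bit-reproducible; profile sets are small enough that Barnes–Hut
  machinery would buy nothing.
* **Missing intensity cells** (`""`/`NA`) are parsed as 0 with a counted
  warning: in MaxQuant-style exports absence means "not detected", and
  max-normalization treats absence and zero identically. This is a
  declared decision, not a silent imputation.

## Problem sizes in the shipped tests

The suite regenerates everything from code: 10,000 random rows for the
normalization invariants, 100 random instances (n ≤ 6) for the
merge-order oracle, 1,000 random count vectors for the cumulative
cut-off oracle, the default ~440-protein gradient (seed 42) for the
recovery experiment, 20 seeds for the endpoint-share calibration and 100
replicates for the early-vs-mid ordering. These sizes make each
statistical property sharp enough to fail loudly while the whole suite
stays fast enough to run on every change.

## Known limitations

* Assignment is winner-take-all against machinery centroids; a protein
  bridging two machineries (e.g. a 70S-spanning factor) gets the single
  best label, not a mixture.
* The screen is correlational. Co-sedimentation is necessary, not
  sufficient, for physical interaction — similarly sized but unrelated
  particles co-sediment, which is why downstream validation exists.
* Reference centroids come from annotated host proteins that pass the
  abundance filter; a sparsely detected machinery (< 3 members) cannot
  be used, by design.
* The cumulative-cutoff rank uses raw summed counts (no transcript-length
  normalization); with highly heterogeneous CDS lengths a
  length-normalized variant of the abundance column would change ranks,
  and the window/cutoff are exposed for exactly that kind of sensitivity
  analysis.
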