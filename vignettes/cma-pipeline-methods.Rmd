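---
title: "Methods: KFERQ motif scanning, SILAC filtering and puncta quantification"
author: "CMAtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KFERQ motif scanning, SILAC filtering and puncta quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CMAtools)
```

CMAtools implements the three computational stages of a chaperone-mediated
autophagy (CMA) substrate screen: scanning protein sequences for KFERQ-like
targeting pentapeptides, filtering SILAC lysosome-proteome quantification
tables into up/down-regulated candidate substrates, and quantifying
fluorescent CMA-reporter puncta per cell in two-channel microscopy images.
Each stage has a synthetic-data generator with full ground truth, so the
whole pipeline can be validated against planted values without access to
primary data.  This vignette records the models, the tunable parameters and
the design decisions behind each stage.

## 1. KFERQ-like motif model

CMA substrates carry a pentapeptide targeting signal recognised by the
HSC70 chaperone.  The composition rule frozen in this package is the one
established in the CMA-targeting-motif literature:

* a glutamine (Q) **anchor** at either end of the 5-residue window;
* the four flanking residues consist of 1–2 **hydrophobic** residues
  (F, I, L, V), 1–2 **basic** residues (K, R) and **exactly one acidic**
  residue (D, E) — four class members in total, no residue outside these
  classes.

Non-canonical, modification-"activated" classes are derived by relaxation:

* **phospho-activated** — not canonical, but becomes canonical when exactly
  one flanking S/T/Y is treated as acidic (phosphorylation adds the missing
  negative charge);
* **acetyl-activated** — not canonical or phospho, but becomes canonical
  when a terminal lysine is treated as the Q anchor (acetyl-K mimics Q);
* **phospho+acetyl** — requires both relaxations at once.

Priority is canonical > phospho > acetyl > phospho+acetyl > none, so every
window receives exactly one class.  Two consequences worth stating: a
window with Q at both ends cannot be canonical (the flanking Q belongs to
no class), and asparagine is *not* accepted as a Q substitute (a documented
choice; the web tools used in the field differ on this point and do not
publish their rule sets, so the rule here is fixed for reproducibility).

`classify_pentapeptide()` implements the rule by vectorised composition
counting over integer-coded windows.  The test suite checks it against an
independently written oracle that literally performs the substitutions
(S/T/Y→D, terminal K→Q) and re-tests the canonical rule, and against an
exhaustive census of all $20^5 = 3{,}200{,}000$ pentapeptides
(`pentapeptide_census()`), whose canonical count has the closed form

$$2 \times \sum_{(h,b) \in \{(1,2),(2,1)\}} \binom{4}{h\,b\,1} 4^h 2^b 2 = 2304.$$

Per-protein reporting collapses window hits to an exclusive category
(`categorize_proteins()`) so that whole-proteome percentages sum to ~100%.
The dual phospho+acetyl window class is folded into both parent classes by
default (`fold_dual = TRUE`); the combinations without an established name
(canonical+phospho, canonical+acetyl) are surfaced under explicit labels
rather than silently merged.  "Proteins with both motif types" rather than
"single windows requiring both modifications" is taken as the meaning of
the combined phospho&acetyl category, because per-protein categories are
what whole-proteome pie charts count.

## 2. SILAC filter cascade

The quantification table is a Proteome Discoverer-style protein export:
linear treatment/control abundance ratio, a p-value, a peptide count and
an FDR-confidence tier per protein.  `apply_filters()` keeps a protein iff

1. confidence is "high" and the peptide count is ≥ 2 — identification
   quality ("high FDR" phrasing in lab reports is read as the standard
   Proteome Discoverer "High confidence" tier, i.e. *low* FDR, because the
   literal reading is self-contradictory;
2. p ≤ 0.05 (inclusive, matching the "≤" restatement used when the filter
   is applied; configurable);
3. the ratio clears a two-sided two-fold change: ratio ≥ 2 or ≤ 0.5, both
   boundaries inclusive, so that `call(r) = up ⇔ call(1/r) = down` holds
   exactly.

Rows whose ratio or p-value cannot be parsed are dropped at read time and
counted in a QC attribute — they are never silently treated as passing.
`summarize_regulation()` computes percentages over up+down calls only, so
the two percentages complement each other.

The synthetic table generator (`gen_quant_table()`) draws per-protein
replicate log2-ratios around a planted effect (|effect| uniform in 1–3
log2 units for regulated proteins; 3 replicates by default, mirroring a
technical-triplicate design) and derives the reported ratio
(2^mean) and p-value (one-sample two-sided t-test) from the same
replicates, so the two are jointly realistic.  By default 90% of proteins
get "high" confidence and 5% single-peptide identifications; the
truth-recovery validations set `frac_high = 1, frac_single_peptide = 0`
because they test the ratio/p cascade, not the identification-quality
lottery — with those arguments and `rep_sd = 0` the recovered up/down sets
equal the planted sets exactly, and at `rep_sd = 0.2` the recall of
proteins with |log2 effect| ≥ 1.5 exceeds 0.95 (n = 1000).

## 3. Puncta-per-cell quantification

The reporter assay produces two channels: DAPI nuclei and a
photoactivatable mCherry CMA reporter whose discrete foci (puncta) each
mark an active CMA lysosome.  The readout is puncta per cell.

The pipeline (`quantify_puncta()`):

1. **Normalization** — min-max rescale of each channel to [0, 1]
   (`normalize_image()`).
2. **Nucleus seeds** — global Otsu on the nuclei channel, connected
   components, area ≥ 50 px; one centroid seed per component
   (`detect_nuclei()`).  Touching nuclei merge into one seed — a known
   limitation, covered by a test.
3. **Cytoplasm segmentation** — foreground from global Otsu of the
   σ = 2 px Gaussian-smoothed reporter channel, then a marker-controlled
   watershed (Meyer flooding, implemented in C++; deterministic FIFO
   tie-breaks) on the Sobel gradient magnitude, one basin per nucleus seed,
   restricted to the foreground (`segment_cytoplasm()`).  The Otsu
   threshold is computed on the smoothed channel *capped at its 95th
   percentile*: rare, very bright punctum pixels otherwise dominate the
   between-class variance and push the threshold above the diffuse
   cytoplasm level, emptying the foreground.
4. **Binarization** — Phansalkar local thresholding,
   $t = m\,(1 + p\,e^{-q m} + k(s/r - 1))$ over a circular radius-15
   neighborhood with mirror padding; constants k = 0.25, r = 0.5, p = 2,
   q = 10 (the widely used Auto Local Threshold defaults; the original
   report names the algorithm but no parameters).  Strict ">" comparison;
   on a constant bright patch the whole patch is foreground — that is the
   formula's behaviour, not an artifact.
5. **Particle analysis** — the mask is computed on a σ = 2.5-smoothed copy
   of the reporter (suppresses pixel noise below the Phansalkar margin),
   opened with a 3-px disc, and split into particles by an intensity
   watershed on a σ = 1-smoothed copy (preserves the saddle between nearby
   spots) — the equivalent of the binary-watershed step applied before
   particle counting in interactive ImageJ workflows.  Particles outside
   [2, 100] px² are rejected; each particle must also rise at least the
   split tolerance above its local threshold (an h-prominence test).  The
   tolerance is max(0.1, 5×the noise sd of the split surface), the noise
   estimated robustly from the residual of the reporter against its
   smoothed copy over the segmented cytoplasm.  Particles are assigned to
   the cell label under their unweighted centroid; centroids on background
   are discarded and tallied (`detect_and_assign_puncta()`).
6. **QC flag** — a cell whose mask covers more than half of its cytoplasm
   is reported with count 0 and flagged: on a field without localized
   bright objects, min-max normalization stretches noise over the full
   scale and the Phansalkar mask degenerates to all-foreground, so there
   are no discrete foci to count.

The two smoothing scales are the pipeline's key numerical choice.  One
scale cannot serve both purposes: heavy smoothing is needed so that noise
stays below the local threshold margin (the margin is at most ≈ 0.05 in
normalized units for these constants), but heavy smoothing also merges the
intensity peaks of spots separated by ~4 spot-sigmas, which must be split.
Computing the mask at σ = 2.5 and splitting at σ = 1 decouples the two.

Group comparison (`compare_conditions()`) applies a classical two-sided
unpaired t-test to per-replicate mean counts — not pooled cells — matching
an n = 4 replicate design.  Degenerate zero-variance groups (possible when
detection is error-free on synthetic fields) return p = 0 or 1 by the
limiting argument rather than erroring.

## 4. Synthetic-data generators: what they emulate, and what not

`gen_cell_image()` renders disk nuclei (radius 12 px, intensity 0.8),
disjoint disk cytoplasms (radius 34 px) with a faint diffuse reporter
level (0.02), Gaussian puncta (σ = 1.5 px) with sub-pixel centers and a
minimum pairwise separation of 4σ, additive Gaussian noise (sd 0.02) and
[0, 1] clipping, on a 512×512 canvas (a desk-scale stand-in for 2048×2048
confocal fields).  snr is defined as peak spot amplitude divided by the
noise sd.  The faint diffuse level — of the order of the noise floor —
models a dark, non-photoactivated reporter background.  The generator
self-checks its truth (puncta inside their cell's mask, disjoint masks,
requested counts) and is bit-identical under a fixed seed.

Not emulated: photoactivation/bleaching kinetics, Poisson photon noise,
3-D stacks, irregular cell shapes, intensity gradients, touching or
overlapping cells, autofluorescence.  Passing the image benchmarks
therefore shows that the segmentation and detection machinery is correct
and well-calibrated for well-separated disk-like cells with Gaussian foci
at snr ≥ 5 — it does not show robustness to the morphological variety of
real micrographs, which is why every threshold in the pipeline is exposed
as a parameter.

`gen_motif_proteins()` plants one motif of a requested class per sequence
on a background drawn only from residues outside every motif class
(A, G, M, P, W, C), so the planted window is provably the only hit; the
generator re-scans each sequence and would resample on any mismatch.  Real
proteomes differ: hits overlap, proteins carry many motifs of several
classes, and background composition is not motif-free.  The scanner
handles those cases (overlapping hits are reported; categories come from
the per-protein class set), but the generator does not exercise them — the
oracle-equivalence and census tests do.

In the all-synthetic end-to-end run, the simulated sequences are
re-labelled with the accessions of the filtered proteins so that the motif
breakdown can be joined against regulation calls exactly as it would be
for a real filtered protein list with downloaded sequences.

## 5. Small quantification utilities

`ddct()` implements relative qPCR expression,
$2^{-\Delta\Delta C_t}$ with $\Delta C_t = C_t^{target} - C_t^{reference}$
per group: invariant to a common Ct shift, and
`ddct(s, c) * ddct(c, s) = 1`.  `normalized_ratio()` divides each
densitometric band by its own loading-control signal before forming the
ratio, making the result invariant to common scanning gain.

## 6. Problem sizes and reproducibility

The validation suite uses 1000-protein tables, 100-sequence proteomes,
and 512×512 fields with 5 cells (100 cells aggregated for the
precision/recall benchmark; 4 replicate fields per condition for the
group test).  `scripts/acceptance.R` recomputes the same quantities from
scratch for any seed.  All randomness flows through explicit seeds;
generators restore the caller's RNG state; `run_pipeline()` reruns are
byte-identical for a fixed config.

## 7. Known limitations

* The motif rule set is frozen from the literature because the web tool
  used for the published analysis does not document its rules; whole-
  proteome percentages can differ from that tool's output in ways that
  cannot be reconciled without its rule set.
* Nucleus pairs closer than the Otsu/connected-component resolution merge
  into one seed, under-segmenting the two cells.
* Min-max normalization discards absolute intensity calibration; the
  all-foreground QC flag compensates on spot-free fields, but fields whose
  true content is a mix of very bright and very faint cells may need the
  per-cell thresholds tuned.
* The per-cell counts undercount slightly when puncta sit closer than
  about 3 sigma of the split surface, where no intensity saddle survives
  smoothing.
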