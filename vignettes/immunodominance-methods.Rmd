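---
title: "Methods: labeling and contrasting immunodominant CDR3 repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: labeling and contrasting immunodominant CDR3 repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunodominance)
```

## The question and the model

When many T cell clones recognize the same peptide–MHC (pMHC) epitope,
one clone usually expands far more than the rest. This package implements
a sequence-level comparison of such **immunodominant (ID)** clones against
their **subdominant (SD)** co-responders: per individual and epitope, the
clonotype with the highest frequency is ID and every other clonotype is
SD. The unit of analysis is the CDR3 amino-acid sequence of the TCR
β chain (α where available), because CDR3 makes the dominant contact with
the pMHC surface.

The comparison proceeds in five stages, each an exported function group:

1. **Ingest** (`parse_vdjdb()`, `filter_records()`): read the VDJdb-style
   TSV dialect in which subject metadata and clonotype frequency sit in
   JSON-typed `meta`/`method` columns; drop naive-phenotype rows
   (CD45RA+CCR7+), rows with no usable frequency, and CD4 rows.
2. **Dominance** (`deduplicate_and_rescale()`, `label_dominance()`,
   `finalize_sets()`): group by a composite subject key, collapse repeat
   measurements, rescale over-unity frequency sums, label per-subject
   maxima ID, apply the rare-clone filter, and remove from the SD pool
   every sequence ever seen as ID.
3. **Regions and features** (`extract_nonvj_aa()`, `extract_nonvj_nt()`,
   `compute_features()`): exact germline trimming into V / non-VJ / J and
   a 22-descriptor physicochemical panel.
4. **Positional enrichment** (`align_cdr3()`, `compute_ppm()`,
   `compute_ples()`): a fixed-width anchored alignment, per-group
   positional probability matrices, and the capped log-enrichment score.
5. **Statistics** (`compare_lengths()`, `normality_check()`,
   `epitope_length_correlation()`, `ad_ksample()`): the distributional
   comparisons used throughout, as tidy one-row results.

A synthetic generator (`synthetic_config()`, `generate_repertoire()`,
`generate_naive_pool()`) produces the inputs with known ground truth; all
tests and the acceptance script run on its output.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_frequency_pct` | 0.01 | rare-clone filter, strictly greater-than: a clone at exactly 0.01% is dropped |
| `interior_min`, `interior_max` | 10, 15 | admissible CDR3 interior lengths (anchors excluded); alignment width is `interior_max + 2` = 17 |
| `cap` | 5 | pLES value substituted for ±infinity when a symbol is absent from one group |
| `log_base` | 2 | base of the pLES log ratio |
| `his_charge` | 0.1 | partial positive charge per histidine in the net-charge count |
| `strict_cd8` | FALSE | whether records with no subset annotation are dropped rather than kept |

Choices behind the less obvious ones:

- **Threshold strictness.** The rare-clone filter removes clones *at or
  below* the threshold (strict `>` keeps only clones over 0.01%), matching
  the phrasing "over 0.01%" rather than "at least".
- **Ties at the top frequency** are all labeled ID. A tie leaves the
  dominant clone genuinely ambiguous; promoting every maximum avoids an
  arbitrary pick and can only make the ID pool conservative (larger).
- **Repeat measurements** of one clonotype keep the **maximum** frequency
  (configurable to the mean). The repeated rows come from the same clone
  re-measured; the maximum is the measurement under which the clone would
  have been called dominant, so keeping it never demotes a true ID clone.
- **Rescaling**: when a subject's collapsed frequencies still exceed 100%
  they are scaled proportionally to sum to 100. Only the ordering matters
  for dominance, and proportional scaling preserves it; the alternative —
  leaving sums above 100% — would make the frequency filter incomparable
  across subjects.
- **Overlap-removal scope.** "Seen as ID elsewhere" is evaluated within
  the same epitope × chain stratum: a sequence dominating a response to
  one epitope says nothing about its role against another epitope, and
  all downstream ID/SD contrasts are per-epitope.
- **Unannotated subsets count as CD8** by default: public tables removed
  CD4 records rather than demanding positive CD8 evidence, and most
  epitope-specific depositions are MHC-I restricted. `strict_cd8 = TRUE`
  implements the conservative reading.
- **Filter-before-or-after labeling.** The frequency filter is applied at
  pool finalization (after labeling), so a subject whose top clone sits
  below the threshold contributes no ID rather than promoting its runner-up.
  `finalize_sets()`'s threshold argument makes the other ordering easy to
  emulate by pre-filtering records.

## The anchored alignment

CDR3s begin at the conserved cysteine (IMGT position 104) and end at the
conserved phenylalanine/tryptophan (118). Sequences failing those anchor
checks are excluded (tallied, not errors). The interior — everything
between the anchors — must span 10–15 residues; IMGT numbering adds
positions in the middle of the loop, so the alignment places
`ceiling(n/2)` interior residues against the C-side, `floor(n/2)` against
the F/W-side, and `15 - n` gaps between them, for a fixed width of 17.

Two length conventions circulate: lengths counted on the full CDR3
(anchors included, the convention of VDJdb `cdr3` strings) or on the
interior. The 10–15 window here applies to the **interior**, which is
what makes "maximum length 15 plus two anchors = 17 columns" arithmetic
exact. Callers who want the window on full strings can pass
`interior_min = 8, interior_max = 13` — the machinery is agnostic; only
the window moves.

The column labels produced by `imgt_position_labels()` are display
decoration (104…118); true IMGT insertion codes (111.1, 112.1, …) are out
of scope.

## PPM, pLES and the capping rule

For `N` aligned sequences, `PPM[k, j]` is the fraction of sequences with
symbol `k` (20 residues + gap) at column `j`; columns sum to 1 exactly.
The enrichment score is the log2 ratio of the ID PPM over the SD PPM.
Zeros are **not smoothed**: a symbol observed in ID but never in SD gives
+5, the reverse −5, and a symbol absent from both groups yields a masked
(NA) cell, distinct from "equally frequent" (0). The cap value 5 reflects
that finite scores rarely exceed magnitude ~4 when both groups are
reasonably sampled (a probability ratio of 16 at base 2); capping keeps
heatmaps readable while remaining clearly outside the finite range. No
pseudocount alternative is offered because the caps are part of the
score's definition, not a numerical fix.

`positive_logo_matrix()` zeroes negative and masked cells and drops the
gap row, producing stack heights for any standard logo renderer.

## The statistics

KS (distribution similarity), two-sided Mann–Whitney (location shifts in
length/hydropathy), Shapiro–Wilk (normality, 3 ≤ n ≤ 5000, degenerate
samples rejected) and Spearman correlation are delegated to the standard
R implementations. The k-sample Anderson–Darling test is implemented in
the package (`ad_ksample()`): the Scholz–Stephens midrank-version
statistic accommodates ties, is standardized by the exact null variance,
and is converted to an approximate p-value by quadratic interpolation of
the published critical-value table on the log scale, floored/capped at
0.001/0.25 outside the tabulated range. Its statistics and p-values were
verified against an independent reference implementation on fixed
fixtures (frozen in the test suite). No multiple-testing correction is
applied anywhere; the stats table counts its comparisons so users can
correct post hoc. Rendered reports suppress p-values above 0.05 (shown
as `ns`); machine-readable outputs always carry the numeric value.

## The synthetic generator: what it emulates, what it does not

The generator is the package's study population. Per subject it draws one
epitope (from an 8-epitope, 8–11-mer viral panel with realistic MHC
restrictions), `clones_per_subject` clones with geometric ranked
frequencies (`ratio` 0.65) normalized to a drawn total between 50 and 95%
— so sums never exceed 100% and each subject has one unambiguous top
clone — and builds each CDR3 as germline V prefix + non-VJ insert +
germline J suffix. Insert residues default to a glycine-enriched
distribution (25% G, small neutral residues over-represented), insert
lengths 0–8 with the bulk at 3–6 residues. Noise knobs inject naive
phenotype rows, JSON-key deletions (subject id, replica id, or frequency
— deletion, not blanking, so the reader's missing-field path is
exercised) and duplicated measurements. Both frequency dialects (`"x/y"`
and percent strings) are emitted deterministically by subject parity.

Optional couplings:

- `length_correlation` ties epitope length to total CDR3 length through a
  Gaussian copula; the insert length is conditioned on the clone's drawn
  germline base length so that V/J length variation does not dilute the
  target rank correlation (residual attenuation from discreteness is
  small, a few hundredths).
- `planted_motif` overwrites one residue at a chosen interior alignment
  column in ID clones (rate `prob_id`) versus SD clones (`prob_sd`).
  When the plant lands inside the germline region, the V+insert+J
  construction identity no longer holds for that clone; planted rows are
  flagged in the truth table, and construction-identity checks use
  unplanted configs.
- `frac_paired` emits matched α records under shared `complex.id`, with
  the α-strictly-longer probability set by `frac_alpha_longer`.

The naive pool is nucleotide-level (germline nt + guanine-enriched insert
+ germline nt), with absolute counts ≥ 1.

What the generator does **not** model: thymic or peripheral selection,
realistic V(D)J recombination statistics (D-segment usage, deletion
profiles, generation probabilities), sequencing error, or cross-subject
sharing beyond what random collisions produce. Passing tests therefore
demonstrate the pipeline's correctness — labels, trims, alignments and
scores do what they claim on data whose truth is known — not that real
repertoires will show any particular biological effect.

The bundled germline reference is likewise a **synthetic stand-in**
(`germline_synthetic.tsv`): gene names follow TRBV/TRAJ nomenclature but
the segments are constructed. Real analyses must supply a reference via
`read_germline()`.

## Numerical choices and degenerate inputs

- Germline trimming is exact longest prefix/suffix; when the V and J
  matches would overlap, the V match wins and the J match is shortened
  (reported via a message). No mismatch tolerance is offered —
  determinism and auditability beat sensitivity here.
- Nucleotide inserts are translated only when in frame (V flank ends on a
  codon boundary and insert length divisible by 3); otherwise the
  translation is `NA`, never a guess.
- Frequency dialects: `"x/y"` → `100·x/y`; `"p%"` → `p`; bare decimals
  are fractions of 1 when ≤ 1 and percent otherwise, covering the three
  conventions seen across depositing studies.
- Net charge is a counting convention (K, R minus D, E plus 0.1 per H),
  documented and configurable rather than a Henderson–Hasselbalch
  calculation.
- Ties in dominance use an exact-equality window of 1e-12 after
  rescaling, so proportional rescaling cannot split a genuine tie.
- Degenerate inputs error early with named messages: empty CDR3s, unknown
  genes (skipped and tallied rather than fatal), all-identical samples in
  Shapiro–Wilk, constant variables in the correlation.

## Problem sizes

The test suite and acceptance script size their simulations to run on a
single CPU in well under half an hour total: cohorts of 10–60 subjects
for unit properties, 300 subjects × 11 clones × 100 seeds for
planted-motif recovery (≥ 95% positive-cell recovery required), 1,000
null simulations at n = 500 per arm for KS calibration (5% ± 2%), and
1,000 random peptides for the brute-force feature oracle (agreement to
1e-9). The `analysis/` scripts narrate the same workflow on a 60-subject
cohort with all noise sources enabled.

## Known limitations

- Overlap removal assumes sequence identity; no clustering of
  near-identical CDR3s.
- The alignment supports one contiguous mid-loop gap block, not full IMGT
  insertion-code numbering; interiors outside 10–15 are excluded rather
  than multi-gapped.
- The Anderson–Darling p-value is a table interpolation, saturating at
  0.001 and 0.25.
- Physicochemical scales are residue-additive means; no pairwise or
  structural terms.
- The pipeline treats strata independently; no sharing of information
  across epitopes and no multiple-testing correction.
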