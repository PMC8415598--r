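---
title: "Column-wise profiling of ankyrin repeats: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Column-wise profiling of ankyrin repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ankprof)
```

## The problem

Tandem repeat proteins such as ankyrin repeat domains (ARDs) are built from
many copies of a short motif — for the ankyrin repeat (ANK), 33 residues
forming a helix-turn-helix with a projecting β-turn. Because every repeat
copy aligns to the same 33 motif positions, data that are far too sparse at
the level of an individual residue (human population variants, structural
coverage, substrate contacts) become statistically powerful when aggregated
over the columns of a repeat multiple sequence alignment. `ankprof`
implements that aggregation end to end: alignment curation, per-column
evolutionary divergence, missense-variant enrichment, structural feature
summaries, contact-map enrichment, substrate-interaction enrichment, and a
final position taxonomy and surface classification.

All statistics operate on tables a practitioner already has (an MSA,
a variant table, DSSP-style structural annotations, Arpeggio-style contact
lists); the package never runs external structure or alignment software.

## Divergence: the Shenkin score

Per-column conservation uses the Shenkin divergence score. With $p_i$ the
gap-excluded frequencies of the $K = 20$ amino-acid types in a column,

$$S = -\sum_i^K p_i \log_2 p_i, \qquad V_{Shenkin} = 2^S \times 6 .$$

A fully conserved column has $S = 0$ and $V_{Shenkin} = 6$; a column with
all 20 amino acids at $1/20$ has $S = \log_2 20 \approx 4.32$ bits and
$V_{Shenkin} = 120$. For interpretability the score is min–max normalised
to 0–100 ($N_{Shenkin}$), anchored by default on the most and least
conserved columns *of the alignment at hand* so the extremes map exactly to
0 and 100; theoretical anchoring on $[6, 120]$ is available via
`normalize_shenkin(anchors = "theoretical")` for cross-family comparison.

Gaps and `X` are excluded from the frequency vector and the remaining
frequencies renormalised. Whether gaps should instead count as a 21st
symbol is a genuinely open modelling choice; exclusion was chosen because
the score is defined over a 20-letter alphabet, and the choice is isolated
in `build_profile()`.

## Enrichment scores: one 2×2 machinery

The missense enrichment score (MES), the protein–protein interaction
enrichment score (PPIES) and intra-repeat contact enrichment all share one
construction. For a focal column (or column group) with $a$ events out of
$b$ opportunities, against $c$ events out of $d$ opportunities pooled over
the remaining core columns:

$$\mathrm{score} = \ln \frac{a/b}{c/d}.$$

For MES, events are missense variant *sites* (each variant site counts
once; distinct variants at one residue do not double-count, and allele
counts are ignored) and opportunities are human residues occupying the
column. For PPIES, events are repeat instances with at least one
inter-atomic substrate contact at the position, opportunities are repeat
instances resolved at the position *in substrate-bound structures*. For
contact enrichment, the per-position sums $C_i = \sum_j c_{ij}$ and
$O_i = \sum_j o_{ij}$ of the filtered contact map play the same roles.

Numerical choices, deliberately uniform across the three scores:

* the 95% CI uses the normal approximation on the log scale of the rate
  ratio (Katz method, $SE = \sqrt{1/a - 1/b + 1/c - 1/d}$), which keeps
  the interval centred on the reported score;
* the p-value is a two-sided Fisher exact test on $(a,\, b-a,\, c,\, d-c)$;
* when any cell of that table is zero, a Haldane–Anscombe $+0.5$ correction
  is applied to every cell for the ratio and CI (the score stays finite);
  the p-value is computed on the uncorrected table;
* per-column p-values are reported unadjusted, with a Benjamini–Hochberg
  column emitted alongside for users who want it.

Site counting (rather than allele weighting) is the default because the
column-level question is "how many independently observed variant positions
does this column tolerate", not "how frequent are those alleles"; an
allele-weighted analysis can be built from the same variant table.

## Alignment curation

Large repeat families defeat one-shot multiple aligners, so the curated MSA
is built by staged sequence-to-profile alignment (`iterative_build()`): a
seed batch of canonical-length (33-residue) sequences defines the initial
core-column profile; each remaining batch is aligned sequence-by-sequence
to the growing profile; sequences that force an insertion *interior to the
core block* are removed, re-aligned once against the updated profile, and
removed permanently if they still introduce gaps; the profile is recomputed
after each batch; finally every removed sequence is aligned to the frozen
final profile and appended, contributing low-occupancy insertion columns.

The internal aligner (`align_to_profile()`) is a three-state affine-gap
Gotoh dynamic program against the log-odds profile
$s_j(a) = \log_2 (p_j(a) / 0.05)$ with pseudocounted frequencies. Defaults:
gap open $-10$ bits, extension $-0.5$ bits, pseudocount 1. The alignment is
global in the profile with free terminal sequence overhangs: N/C-terminal
extensions therefore sit outside the core block and are never grounds for
removal — only interior insertions count, since only those would force gap
columns onto every other row. One re-alignment attempt before permanent
removal, and per-sequence alignment (rather than a profile-to-profile
merge) for the final re-append, are pragmatic choices where the exact
behaviour of production aligners is tool-internal; neither is claimed
equivalent to any external program.

Column occupancy filtering (`filter_columns_by_occupancy()`) is a strict
greater-than comparison, default threshold 0.5%.

## Structural features

* **Quality filter**: residues are kept iff RSCC $> 0.85$ and RSRZ $< 2$,
  strict inequalities; records missing either metric are dropped and
  counted.
* **RSA**: DSSP absolute accessible surface area divided by the Tien et al.
  (2013) *theoretical* MaxASA for the residue type (the theoretical table
  is the common default and is shipped as versioned data;
  values above 1 are legitimate and pass through). Classes: buried
  (RSA ≤ 5%), partially exposed (5% < RSA < 25%), surface (RSA ≥ 25%);
  boundaries inclusive of the outer classes.
* **Per-column summary**: 8-state DSSP frequencies with argmax consensus
  (ties resolved in the fixed order H, G, I, E, B, T, S, C); median RSA
  with a bootstrap 95% CI (1000 resamples, seeded per position so results
  are reproducible).
* **β-turn typing**: nearest ideal type among I, I′, II, II′, VIII from
  the inner residues' φ/ψ, with ±45° per-angle tolerance and ±90° on
  ψ(i+1). These windows follow the familiar turn-classification
  convention; the tolerance is a convention choice, configurable in code,
  not a reproduction of any particular study's unstated windows.
* **Asx motifs**: an Asx-β-turn requires Asn/Asp at motif position 27 with
  a side-chain↔backbone-N hydrogen bond to position 29; the type 1 β-bulge
  loop with Asx requires Asn/Asp at position 32 bonded to the backbone N of
  both downstream positions (1 and 3 of the following repeat — spans
  crossing the repeat boundary wrap modulo 33). Hydrogen bonds are consumed
  from the contact table, not recomputed from geometry.

## Contact analysis

Contact evidence is binary at the repeat level: $c_{ij}$ counts repeats
with ≥1 atomic contact between motif positions $i$ and $j$ (however many
atom pairs are involved), $o_{ij}$ counts repeats where both positions are
structurally resolved, and the normalised map is $c_{ij}/o_{ij}$. The
producer of the contact table is responsible for the 5 Å atomic cutoff; the
reader validates it. Before enrichment, trivial neighbour contacts are
removed: pairs with $|i-j| \le 6$ are zeroed (in both $c$ and $o$), leaving
the 351 long-range pairs of a 33-position motif. Inter-repeat contact
enrichment is deliberately not part of the default pipeline; the same
machinery accepts `partner_class = "inter_repeat"` records if a user wants
it.

Binding modes are evaluated per protein only when at least 2 distinct
repeats and 4 distinct residues contact the substrate; the mode is the
surface (concave/convex/basal) holding at least τ = 2/3 of the binding
residues, else mixed. τ quantifies "dominates", which is not otherwise
pinned down; it is a configuration value and is logged with every run.

## Position taxonomy and surfaces

Columns are labelled CMD/CME/UMD/UME by combining $N_{Shenkin}$ and MES:
conserved means $0 \le N_{Shenkin} \le 25$, unconserved means
$75 \le N_{Shenkin} \le 100$ (both boundaries inclusive), depleted/enriched
means MES strictly negative/positive; MES exactly 0, or divergence between
the windows, gives "none". Classification uses the MES point estimate, with
the CI reported alongside; requiring the CI to exclude 0 is available as a
strict mode in downstream filtering (the null-calibration test shows why
the point estimate alone must be read together with its CI).

The default surface map assigns the 33 positions to core (9 positions:
4, 5, 6, 7, 9, 10, 17, 18, 21), concave (8: 1, 2, 3, 8, 11, 12, 32, 33),
convex (9: 13, 14, 15, 16, 19, 20, 22, 23, 24) and basal
(7: 25, 26, 27, 28, 29, 30, 31). `suggest_ridges()` scans per-column median
RSA (default threshold 0.45) for high-accessibility non-core positions —
the ridge positions that delimit surfaces — as an advisory aid when porting
the analysis to other repeat families; it never overrides the map.

## The synthetic-data generator

Every statistical property of the pipeline is tested against synthetic data
with known ground truth (`synthetic_truth()` + `generate_*()`):

* **Alignment**: one categorical amino-acid distribution per column,
  sampled once from a Dirichlet whose concentration encodes conservation
  (low total α ⇒ conserved), then rows drawn i.i.d. — a star phylogeny.
  This matches the exchangeability assumption of the column statistics and
  is exactly the regime in which the enrichment machinery is calibrated.
* **Variants**: each human residue at column $i$ is a variant site with
  probability $r \cdot e^{\delta_i}$ (baseline $r = 0.1$ per residue by
  default — a desk-scale rate giving tens of events per column at a few
  hundred human rows; effects $\delta_i$ are the recoverable truth).
  A probability above 1 is an error naming the column rather than a silent
  cap, so planted effects always remain recoverable. Allele counts are
  fixed at 1, matching site-count scoring.
* **Structures**: per-column RSA from Beta(mκ, (1−m)κ) with default
  κ = 10; secondary structure from per-column 8-state distributions; φ/ψ
  from canonical per-state angles with ±15° uniform jitter; a configurable
  fraction (default 10%) of residues planted to fail the quality filter.
  Repeats are grouped into synthetic "structures" of 4 (a small ARD) so
  binding-mode logic sees multi-repeat proteins; half of the structures are
  substrate-bound by default.
* **Contacts**: intra-repeat contacts Bernoulli per pair from a symmetric
  probability matrix (default decaying with sequence separation);
  substrate contacts Bernoulli per column for repeats of bound structures.

What the generator does **not** emulate: phylogenetic correlation between
rows, linkage between variants, realistic 3D geometry, mutation-model
biases, or correlated quality failures. Tests passing on this generator
therefore demonstrate that the statistical machinery is correct and
calibrated under its stated assumptions — not that real repeat families
satisfy those assumptions. On real data, row non-exchangeability (deep
paralog structure) will widen true sampling variability relative to the
reported CIs.

## Study sizes used by the automated checks

The test-suite calibration and recovery studies use desk-scale sizes chosen
to give adequate counts per cell while keeping every check quick to re-run:
one alignment of 500 human rows at baseline rate 0.1 (≈50 events per
column) with 200 replicate variant draws for null calibration (6,600
Fisher tests; observed p < 0.05 rate within 0.05 ± 0.02); 31 replicates ×
33 columns (1,023 simulated columns) for CI coverage of planted effects
drawn uniform on ±0.7; and 20 replicates at 2,000 bound repeats for group
PPIES recovery (planted concave-vs-rest log-ratio 1.8; mean absolute error
of the recovered score below 0.1). The aligner is checked exhaustively
against an enumeration oracle on small profiles, where enumeration is
exact.

## Degenerate inputs and tie-breaks

Empty alignment columns are flagged and excluded from scoring and from
normalisation anchors. Zero-range normalisation (all columns identical) is
an error rather than a silent 0/0. Zero cells in enrichment tables take the
Haldane correction as above. Alignment traceback ties prefer match over
deletion over insertion, making outputs deterministic; bootstrap and all
generators are seeded, and `run_pipeline()` with a fixed seed is
byte-identical across runs (no timestamps enter any output file).

## Limitations

* The curation stage approximates, but does not reproduce, any external
  aligner; on real families the removed-sequence set will differ from what
  ClustalΩ-based pipelines report.
* Enrichment CIs assume independent Bernoulli events per residue; repeats
  within one protein are not independent in reality, so real-data CIs are
  optimistic.
* The surface map and taxonomy thresholds are motif-specific defaults for
  the 33-position ankyrin repeat; other families need their own map (the
  machinery accepts any position→surface table).
* Hydrogen-bond-dependent calls (Asx motifs) are only as good as the
  upstream contact table's atom classification.
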