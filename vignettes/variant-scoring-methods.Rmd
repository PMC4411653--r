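---
title: "Scoring coding variants with amphiphilic pseudo amino acid composition"
author: "pseaacvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring coding variants with amphiphilic pseudo amino acid composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseaacvar)
```

## The problem

Exome and gene-panel sequencing produce thousands of coding variants per
sample, most of which are benign. `pseaacvar` estimates, for each variant
and each transcript isoform it hits, the probability that the resulting
protein change damages protein function, and labels the variant
*damaging* (posterior ≥ 0.5) or *tolerated*. The distinguishing idea is
the sequence representation: instead of relying on homology or
precomputed substitution matrices, the wild-type and mutant peptides
around the change are encoded as *amphiphilic pseudo amino acid
composition* (PseAAC) vectors, and their element-wise difference is the
core feature block of a random-forest classifier. Because the encoding
works on arbitrary peptides, the same model scores missense changes and
insertions/deletions up to 60 nt — variant types that alignment-based
missense-only tools cannot score.

## From genome to peptide space

A variant is projected onto each transcript whose CDS it overlaps. The
package edits the chromosome sequence, rebuilds the spliced CDS with
coordinates shifted past the edit, and translates wild and mutant
proteins. The mutant translation does not stop at the annotated CDS end:
after a frameshift or a lost stop codon, downstream exonic and then
genomic sequence is read until the first in-frame stop (capped at 9 kb),
so the mutant protein is always stop-free and ends at its first stop.
The change is classified as synonymous, missense, in-frame
insertion/deletion/indel, frameshift, stop-gain or stop-loss by
comparing frames and protein lengths.

Two degenerate geometries are rejected rather than guessed at: indels
that span a splice junction and indels that disrupt the start codon.
The projection of such variants onto the protein is ill-defined without
a splicing model, so they are reported as unsupported instead of being
scored with an arbitrary convention.

## The snippet and its encoding

Around the first changed residue, up to 20 residues of flanking context
are taken on each side — a 41-residue snippet in the interior of a
protein, truncated (never padded) at the termini. The window size
reflects the length scale of short functional motifs and their flanking
regions; it is fixed, not tuned.

Each snippet `P = A1 A2 … AL` is encoded as a vector of `20 + 2λ`
components. The first 20 are the amino-acid frequencies `f_u`. The tail
holds tier correlation factors built from two residue property scales,
hydrophobicity `h1` (Tanford-style values) and hydrophilicity `h2`
(Hopp–Woods values), each normalized to mean 0 and unit standard
deviation over the 20 amino acids (population convention, denominator
20, as in the amphiphilic PseAAC literature). For tier `k = 1..λ`:

```
tau[2k-1] = mean over i of h1(A_i) * h1(A_{i+k})
tau[2k]   = mean over i of h2(A_i) * h2(A_{i+k})
```

and the full vector is

```
p_u = f_u / D            (u ≤ 20)
p_u = w * tau_{u-20} / D (20 < u ≤ 20+2λ),   D = sum(f) + w * sum(tau)
```

so every vector sums to 1. One numerical choice deserves a note: some
formulations *sum* the tier products instead of averaging them. We
average by the number of coupled pairs `L − k`, which keeps tiers
comparable when a snippet is shorter than 41 residues (anywhere near a
protein terminus); the raw-sum variant remains available via
`tau_average = FALSE` for parity experiments.

The variant's sequence feature block is the element-wise
**wild − mutant** difference of the two snippet encodings (the sign is a
fixed convention; the classifier is indifferent to it). A synonymous
change gives the zero vector, which is why synonymous variants carry no
training signal and are excluded.

## The full feature vector

To the PseAAC difference (length `20 + 2λ`) are appended six scalars:

* `len_diff`, `len_ratio` — mutant-minus-wild protein length difference
  and mutant/wild ratio; truncations push both down, stop losses and
  insertions push them up.
* `norm_pos` — the first changed residue index divided by the wild
  protein length (0.9 for residue 90 of a 100-residue protein); early
  truncating changes matter more than late ones.
* three per-base evolutionary conservation scores (GERP++-, phyloP- and
  SiPhy-style tracks supplied as bedGraph). For SNVs the score at the
  substituted base; for deletions the maximum over the deleted bases;
  for insertions the maximum over the two flanking bases. Multi-base
  substitutions take the maximum over substituted bases, extending the
  deletion rule. A missing track value is imputed as 0 (the neutral
  point of these scores' conventional scaling) and flagged in a column
  that is *not* fed to the classifier.

At the default `λ = 12` the vector has `20 + 24 + 6 = 50` dimensions;
the tuning grid spans 30 (λ = 4) to 66 (λ = 20).

## Classifier, tuning and the short-sequence rule

`fit_classifier()` fits a random forest (default) or a logistic
regression and returns an object with the usual `print`, `summary`,
`predict`, `coef` and `plot` methods. The damaging score is the forest's
posterior probability for the damaging class; 0.5 is the decision point,
with ties counted as damaging. The published hyperparameter optimum —
`w = 0.1`, `λ = 12`, 250 trees, 2 features per node
(`default_params()`) — is the default. `tune_classifier()` re-runs the
grouped 10-fold cross-validated grid search (`default_grid()`: trees
5–350, features per node {heuristic, 2, 4}, λ {4,8,12,16,20}, w
{0.5, 0.1}) through an encoder callback, because changing λ changes the
feature dimensionality. Selection is by CV accuracy with ties broken by
AUC and then by the smaller model. The grid's "heuristic" entry is
interpreted as the standard `floor(log2(p)) + 1` features-per-node rule;
a literal `floor(log(trees)) + 1` mode is kept behind a flag for
comparison, since printed descriptions of this heuristic vary.

A mutant peptide shorter than `λ + 1` residues cannot be represented in
PseAAC at all. That situation only arises when a premature stop lands
within the first few codons, and such variants are labeled damaging
outright with score 1.0 (`rule_score()`, `source = "rule"`) rather than
being forced through the encoder.

## Dataset construction

`assemble_dataset()` applies the curation filters before training:
damaging candidates seen at background population frequency above 5%
are dropped (likely mislabeled), tolerated candidates must be common
(frequency > 0.05), synonymous rows are removed from both sides, and
tolerated duplicates across sources are deduplicated. Every removal is
counted in a provenance ledger so `initial − removed = final` is
checkable. Frameshift and stop-causing/disrupting variants are kept for
the final model but excluded from balanced evaluation sets
(`exclude_fr_sc_sd = TRUE`), since their gross class imbalance would
otherwise dominate the comparison. Quasi-balanced sets are produced by
capping the majority class at 1.3× the minority at the group level
(`balance_classes()`); the cap ratio is configurable because the exact
historical balancing procedure is not recorded anywhere we could
reimplement from.

Train/test splits are *grouped*: all transcript-isoform rows of one
genomic variant (`group_key = chrom:pos:ref:alt`) land on one side, so
near-duplicate rows can never leak across the split. The split shuffles
groups under a seed and cuts as close to the 70% row fraction as group
sizes allow.

## External predictors and the vote

PolyPhen2 and SIFT scores, when available, are folded in. Each raw
score is standardized piecewise-linearly around the tool's decision
threshold — PolyPhen2 0.447 (damaging-high), SIFT 0.05 (damaging-low) —
so the tolerated side maps onto [0, 0.5), the damaging side onto
[0.5, 1], endpoints stay endpoints and the threshold lands exactly on
0.5. A score exactly at the threshold counts as damaging, mirroring the
classifier's own convention at 0.5. These threshold assignments follow
both tools' published conventions and reproduce the package's worked
examples; we note that prose descriptions sometimes list the two
numbers in the opposite order, which fails both checks.

`vote_ensemble()` then decides: with all three scores present, the
majority class wins and the reported score is that of the most
confident tool (largest |score − 0.5|) *among the majority voters* — a
deliberate restriction, since picking the most confident tool overall
could report a score on the losing side of its own class call. With one
external score missing, the more confident of the two remaining tools
sets class and score; with both missing, the classifier stands alone.
Every variant therefore always receives a prediction.

## The synthetic study generator

`simulate_study()` fabricates everything the pipeline consumes: a toy
two-chromosome genome with single- and multi-exon genes on both strands
(valid start/stop, stop-free ORFs), labeled variants, three
conservation tracks and mock external scores — all deterministic from
one seed. Its defaults are the package's study conditions:

* 2000 variants over 30 genes of ~250 codons, half damaging
  (`damaging_fraction = 0.5`), 10% indels up to 12 nt.
* Damaging SNVs choose among the nine single-base codon substitutions
  with probability ∝ `exp(+2 s (|Δh1| + |Δh2|))`, tolerated ones with
  `exp(−2 s ·)`, where `s` is `signal_strength`. At `s = 1` damaging
  changes are almost always the largest available hydropathy shift and
  tolerated ones the most conservative; at `s = 0` the two classes are
  exchangeable. This plants the signal through the very scales the
  encoder uses, so classifier recovery is a direct test that the PseAAC
  encoding transmits hydropathy information.
* Conservation tracks are smoothed noise with a moderate elevation
  (e.g. +1.5 on the GERP-like track at `s = 1`) at damaging sites —
  informative but deliberately overlapping, so the conservation block
  assists rather than dominates and ablating it costs only a few AUC
  points.
* Frequencies come from a two-component mixture (95% of damaging rare,
  5% common; the reverse for tolerated candidates) so both dataset
  filters are exercised.
* Mock external tools call the planted label correctly with probability
  `external_accuracy` (default 0.9) and are missing at a configurable
  rate (default 10%).

What the generator does *not* emulate: real substitution processes
(no codon usage, no transition/transversion bias), linkage, realistic
population frequencies (labels' props, not evolved quantities),
overlapping genes or alternative isoforms, and conservation scores
computed from actual alignments. Passing the recovery tests therefore
shows that the pipeline is correct and that the encoding carries a
planted physicochemical signal — not that real pathogenic variants are
this separable.

## Problem sizes and numerical choices

The packaged tests run the generator at 120–2000 variants and verify
the encoder against an independently coded brute-force evaluation of
the PseAAC definition to 1e-10 on random snippets; recovery checks use
ten seeds at 2000 variants each, with the tuned defaults rather than a
full grid re-search per seed (the grid search itself is exercised on
restricted grids). Scale normalization tolerances are 1e-9. Degenerate
inputs fail loudly: a constant property scale (zero variance), an
unknown residue symbol, a zero PseAAC denominator, a single-class
training set and a single-group split all raise errors naming the
problem.

## Known limitations

* Variants hitting several overlapping transcripts are scored
  independently per transcript; no canonical-isoform aggregation is
  offered.
* Splice-junction and start-codon indels are reported as unsupported,
  not scored.
* The conservation imputation (0 for missing) is neutral for GERP-like
  scales but not for strictly positive scales such as SiPhy's; the
  missingness flag column lets downstream users filter.
* Selenoproteins and non-standard genetic codes are not handled.
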