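---
title: "Screening proteomes for putative ITIM/ITSM-bearing inhibitory receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for putative ITIM/ITSM-bearing inhibitory receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irminer)
```

## The screening problem

Most immune inhibitory receptors signal through immunoreceptor
tyrosine-based inhibitory or switch motifs (ITIM/ITSM) in their
cytoplasmic tails: short linear motifs that, once phosphorylated, recruit
the phosphatases SHP-1, SHP-2 or SHIP-1 and dampen activating signalling.
The motif is weakly constrained — `(V|L|I|S)xYxx(I|L|V)` for the ITIM,
extended to allow `T` at position 1 for the ITSM — so a naive scan of a
proteome produces thousands of spurious matches. `irminer` implements a
screen that whittles a proteome down to plausible inhibitory-receptor
candidates by demanding, in order, that a protein

1. is short enough for reliable topology prediction (≤ 10,000 residues);
2. carries at least one consensus motif;
3. is an integral membrane protein with at least one motif entirely
   inside a cytoplasmic segment;
4. carries more motifs than its residue composition alone would explain
   (a composition-preserving permutation test);
5. has at least one motif in a low-confidence (likely intrinsically
   disordered) region of its predicted structure (mean pLDDT < 80).

Surviving genes can then be classified into functional categories from
resting/activated expression data.

## Motif scanning

`scan_motifs()` reports **every** matching 6-residue window, including
overlapping ones. The count of motifs is therefore "number of matching
windows", which is the simplest well-defined notion of occurrence, and —
crucially — the identical counter is used inside the permutation null
(`count_motifs_in_domains()`), so the test statistic is internally
consistent. Ambiguity codes `X`/`U` are accepted in sequences but never
satisfy a constrained position (1, 3, 6): ambiguity must not create
evidence. They do satisfy wildcard positions.

A hit whose first residue is `T` is labelled ITSM; the two classes are
treated identically downstream, and both enter every count.

`scan_itam_embedded()` additionally flags motifs whose tyrosine is part
of an ITAM arrangement `Yxx(I|L) x6–12 Yxx(I|L)` (6–12 residues between
the end of the first half-site and the second tyrosine). Because
ITAM-bearing molecules are not necessarily inhibitory, the flag is an
annotation only and never used as a filter.

## Topology

Topology strings use the TOPCONS per-residue alphabet: `i` cytoplasmic,
`o` extracellular, `M` membrane, `S` signal peptide. The protein class is
derived from the membrane-segment runs: none → `no_tm`, two or more →
`multi_pass`, one → single-pass, with the orientation read off the state
on the N-terminal side of the segment (`i` → type II, otherwise type I;
a signal peptide counts as the non-cytoplasmic side).

A motif is retained only when **all six** residues are in `i` state.
This is the strictest reading of "the motif lies in an intracellular
section"; it avoids counting tyrosines that are partly buried in the
membrane. It also makes the observed count equal to the motif count of
the extracted intracellular domains, which is what the permutation test
shuffles.

Topology is consumed as given. Mispredicted topologies (the known
receptor MPIG6B is the classic example: its transmembrane helix is
mispredicted in the ITIM-bearing isoforms, so the topology filter loses
it) are an upstream problem; the packaged known-receptor reference
(`load_known_receptors()`) flags MPIG6B for exactly this reason.

## The permutation null

Large proteins, or proteins rich in tyrosines and hydrophobic residues,
contain consensus windows by composition alone. For each protein with at
least one intracellular motif, `permutation_likelihood()` shuffles the
residues of each intracellular domain uniformly at random (Fisher–Yates;
composition is preserved exactly), recounts motifs, and estimates

> likelihood = P(shuffled count ≥ observed count)

over `n_permutations = 10000` iterations. Counting "greater or equal"
makes this a valid permutation p-value (the identity arrangement always
reproduces the observed count). Proteins are excluded when the
likelihood exceeds `0.25 + ε`, with ε drawn once per protein from
Uniform[0, 0.01) out of the seeded run RNG and recorded in the result,
so every borderline decision is reproducible. The jitter randomises
decisions for proteins sitting exactly at the calibrated 0.25 cutoff;
with 10,000 permutations the Monte-Carlo standard error near 0.25 is
about 0.004, of the same order as the jitter.

Two open choices were closed as follows:

* **Multi-domain proteins.** Each intracellular domain is shuffled
  independently and counts are summed (`shuffle_mode = "per-domain"`,
  the default). This preserves the domain length structure and cannot
  create motifs spanning a membrane segment. A `"concatenated"` mode
  (pool, shuffle, re-split) is provided for sensitivity analysis.
* **Motifs during permutation** are counted within single domains only,
  consistent with per-domain shuffling.

`exact_likelihood()` is the package's brute-force oracle: for domains of
up to 9 residues it enumerates all position permutations (identical
letters weighted by multiplicity) and returns the exact probability. For
the domain `SAYAAL` with one observed motif the exact value is 1/120 ≈
0.00833 — of the 720 position permutations, exactly the 6 arrangements
of the three alanines around the fixed `S·Y··L` skeleton contain a
motif. The test suite checks the Monte-Carlo estimator against this
oracle at the 3-sigma binomial bound on dozens of random short domains.

No multiple-testing correction is applied across proteins: the threshold
is a calibrated inclusion cutoff, not an error rate.

## Structure confidence

Short linear interaction motifs function predominantly in intrinsically
disordered regions. AlphaFold's per-residue confidence (pLDDT, 0–100)
doubles as a disorder proxy: low-confidence regions are likely
disordered. `read_plddt()` extracts per-residue pLDDT from the B-factor
column of an AlphaFold-convention PDB file (single model, single chain,
gap-free numbering; the value is taken from the CA atom and all atoms of
a residue must agree to within 1e-3). A motif's score is the arithmetic
mean over its six residues; a protein passes when **any** motif scores
strictly below 80.

The boundary is strict: a mean of exactly 80.0 is excluded. Means below
50 are additionally flagged as likely disordered. Both cutoffs are
configurable (`plddt_threshold`), and lowering the threshold can only
shrink the passing set (a monotonicity the tests assert).

One caveat is surfaced here deliberately: the structure predictions
treat each protein in isolation. Motifs may become accessible only after
conformational change on ligand binding, or may be unusable in
complexes, and a per-residue confidence score knows nothing of either.

## Expression categories

From resting/activated expression of isolated immune-cell subsets, genes
are classified per cell type:

| resting | activated | log2FC | category |
|---|---|---|---|
| – | – | any | `not_expressed` |
| – | + | any | `negative_feedback` |
| + | + | [−0.5, 0.5] | `threshold` |
| + | + | < −0.5 | `threshold_disinhibition` |
| + | + | > 0.5 | `threshold_negative_feedback` |
| + | – | any | `threshold_disinhibition` |

"Expressed" means strictly above the median of **all** genes in the
condition — the median must come from the dataset's full gene universe,
never from the candidate list alone. The boundary value 0.5 belongs to
the closed `threshold` interval, since the outer categories are defined
by strict inequalities. The classification is a total, single-valued
partition of (expressed-resting, expressed-activated, log2FC).

Counts are normalised by the median-of-ratios size-factor method and
log2(x+1) transformed; TPM data are log2(x+1) transformed directly. The
pseudocount 1 keeps zeros at zero; log2FC is the difference of
per-condition means on that scale. Because "average expression per
sample" versus "expressed within the sample" is ambiguous when a
condition holds several samples, the default compares per-condition
means against the median of per-condition means
(`call_mode = "condition-mean"`, one value per gene × cell type ×
state); a `"per-sample-majority"` alternative calls a gene expressed
when it beats the within-sample median in a strict majority of the
condition's samples.

Genes absent from a dataset are reported as `not_detected`, which is
deliberately distinct from `not_expressed`.

For tumour-infiltrating T-cell data that arrive as cell × gene Z-scores
with subset and subcluster labels, `tumour_subset_expression()` averages
within subclusters, combines subclusters by their relative contribution
(weights summing to 1 per subset), and calls a gene expressed when the
weighted mean Z-score is strictly above 0. An alternative rule —
expressed when above the gene's median across subsets — is exposed as
`rule = "median-across-subsets"` because both readings circulate; the
Z-score rule is the default.

## Synthetic fixtures: what they emulate and what they do not

All fixtures are pure functions of their parameters and a seed.

**Proteomes** (`make_synthetic_proteome()`): topology strings are built
from segment runs consistent with the requested class; background
residues are uniform over the 20 amino acids with a rejection step that
re-draws the tyrosine of any accidental consensus window, so planted
motifs are exact ground truth. Cytoplasmic segments are drawn from a
polar, tyrosine-free alphabet — real cytoplasmic tails are enriched in
polar, disorder-promoting residues, and the choice guarantees that a
planted motif is the only possible intracellular window, giving planted
proteins unambiguous (low) permutation likelihoods. For designed
permutation failures, `ic_composition = "motif_rich"` builds a
deterministic tail — one motif, then a tyrosine block and a
valine/leucine block spaced by glutamates — whose original arrangement
contains exactly one window but whose composition makes shuffled windows
highly likely; its permutation likelihood sits far above the 0.25
threshold (empirically 0.7–0.95) for any seed.

**Structures** (`make_synthetic_structure()`): valid single-chain PDB
files whose every atom carries the prescribed per-residue pLDDT at the
PDB's %6.2f precision; coordinates are an extended (trivially
self-avoiding) walk because geometry is irrelevant to confidence
scoring.

**Expression** (`make_synthetic_expression()`): background genes with
log-normal baselines (log2 mean 5, sd 2) define the condition median;
planted genes sit at log2 ≈ 8 (above) or ≈ 2 (below) per their category,
with the planned log2FC applied on activation and Gaussian noise (sd
0.1 by default) added before converting back to counts. The classifier
depends only on median ranks and differences, so the absolute scale is
arbitrary.

What the fixtures do **not** emulate: real residue composition and
homology structure, isoform families sharing genes by default, correlated
expression noise, library-size imbalance beyond what size factors absorb,
and — most importantly — the error modes of upstream predictors
(topology misprediction, structure failure). Passing tests on fixtures
therefore demonstrate that the pipeline's logic is correct, not that its
thresholds generalise to any particular proteome release.

## Problem sizes and numerical choices

The shipped tests run the scanner/oracle equivalence on 1,000 random
sequences of length ≤ 200; the permutation calibration on `SAYAAL`
across 10 seeds and on 50 random short domains at 10,000 permutations
against exact enumeration; and the end-to-end fixture with 10 proteins
(one designed failure per stage). These sizes keep the full suite under
a minute while leaving every stochastic check with conventional 3-sigma
headroom. The pipeline default remains 10,000 permutations per protein.

Other numerical conventions, collected in one place: coordinates are
1-based closed intervals throughout; the length filter is inclusive at
10,000; the likelihood filter keeps `likelihood ≤ 0.25 + ε` (inclusive);
the pLDDT filter passes `mean < 80` (strict); fold-change boundaries
±0.5 are inclusive for `threshold`; expression calls are strictly above
the median; tumour calls are strictly above 0. Gene-level aggregation
keeps the isoform with the lowest permutation likelihood, tie-broken by
lowest minimum motif pLDDT, then lexicographic protein id. Proteins that
pass the permutation filter but lack a structure are carried with status
`"no-structure"` rather than dropped, since structure-prediction
failures are recoverable upstream and silent loss would bias the screen.

## Limitations

The screen inherits every upstream bias: topology predictions (MPIG6B),
structure confidence as a disorder proxy, and the in-vitro stimulation
conditions behind the expression categories. It considers only
ITIM/ITSM-type motifs — inhibitory receptors signalling through other
motifs (CD200R) or unassigned tyrosines (TIM-3) are invisible to it. The
candidate list is a prioritisation, not a validation.
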