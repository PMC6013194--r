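---
title: "Models and methods behind the MYB-superfamily census"
author: "mybcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the MYB-superfamily census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what each stage
computes, the assumptions it makes, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices that would otherwise be invisible in the code.

## 1. The census problem

MYB-superfamily transcription factors are defined by 1–4 adjacent
imperfect tandem copies of a ~50–53 residue DNA-binding repeat. The repeat
count partitions the family into subfamilies — MYB-related (1R), R2R3
(2R), R1R2R3 (3R), 4R — plus an atypical class whose members carry only a
fragment of a repeat. A genome-wide census asks, for an annotated
proteome: which proteins belong to the family, in which subfamily, in
which phylogenetic group, with what motif and exon/intron architecture,
where on the chromosomes, with which orthologs/paralogs relative to a
reference species, and how the genes behave across fruit development. Every
stage of that battery is implemented here; the synthetic generator gives
each stage a ground truth to be verified against.

## 2. Repeat detection (PSSM scan)

**Model.** The scanner is a position-specific scoring matrix (PSSM) over
the 20 standard residues, built from a seed alignment of repeat copies.
Columns with more than 50% gaps are dropped; each retained column scores
residue *a* as `log2(((n_ja + p·b_a) / (n_j + p)) / b_a)` with pseudocount
mass `p` (default 1) and background `b` (default uniform). A PSSM has no
insert/delete states; this is a deliberate simplification relative to a
full profile HMM. It is accurate when repeat copies do not carry internal
indels — which holds for the synthetic generator and approximately for
real MYB repeats, whose length varies by only a few residues — and it is
the documented fidelity trade-off of this package.

**Thresholds.** Published family censuses rarely state their search
cutoffs, so the scanner calibrates itself: windows of a long random
background sequence are scored at every sub-profile width, and the
threshold per width is `mean + z·SD` of that null (z = 5 by default),
floored at 0 bits. The floor matters: the null distribution of window
scores is strongly left-shifted (a random window matches almost no
columns), so `mean + 5 SD` can be far below zero while the null's *right*
tail is heavier than Gaussian; requiring a positive bit score — the window
must be likelier under the profile than under the background — is the
standard convention and removes the false partial hits the Gaussian rule
would admit.

**Partial repeats.** Truncated repeats are detected by scoring prefix and
suffix sub-profiles covering at least 40% of the profile width, at every
position. Restricting partial hits to sequence termini was considered and
rejected: genuinely truncated repeats (the atypical class) can sit
anywhere in a protein, and the planted ground truth places them in random
background.

**Overlap resolution and completeness.** All candidate placements compete
greedily by bit score (ties: leftmost start). Because scores are log
likelihood ratios, each placement effectively competes at its
maximum-likelihood width: a genuinely truncated repeat out-scores the
full-width window that straddles it plus background, while a full repeat
out-scores its own trimmings. A hit whose retained width reaches
`complete_min` (default 0.8) of the profile counts as a complete repeat:
with imperfect repeats the ML width trims terminally substituted columns
(typically 0–3), so trimmed full repeats sit at completeness ≥ 0.9,
clearly above genuinely truncated fragments (≤ 0.6 in the generator, and
"part of a repeat" biologically).

**Classification.** Subfamily is the length of the longest run of complete
hits whose inter-hit gaps are at most `max_adjacent_gap` residues (default
30 — repeats in this family are adjacent; the knob is exposed). One
repeat = MYB-related, two = R2R3, three = R1R2R3, four = 4R; more than
four is reported as 4R with a flag; only partial hits = atypical; no hits
= not a family member. When a FASTA contains several isoforms per locus
the longest is kept (`representative_per_gene()`).

## 3. Alignment, trees and group assignment

**Alignment.** Pairwise global alignment (BLOSUM62, gap open 10, extend
0.5 — ClustalW-like defaults) and local Smith–Waterman alignment are
computed with Biostrings; progressive multiple alignment calls the mafft
executable, which is deterministic for a fixed input set. Distances are
p-distances with pairwise gap deletion — the common default for
distance-based protein family trees; a model correction can be layered on
the distance matrix by the caller if desired.

**Neighbor joining.** The Saitou–Nei agglomeration is implemented in the
package (the tie-break and clamping behaviour are part of the method's
contract): join the pair minimizing `Q(i,j) = (n−2)d(i,j) − R_i − R_j`,
branch lengths by the standard split formula, negative branch lengths
clamped to zero with the deficit moved to the sibling so the joined pair's
path length is preserved, and ties broken by the label-sorted pair so the
tree is reproducible. On additive matrices the result reproduces the
generating tree metric exactly (tested by round trip on random trees and
cross-checked against an independent NJ implementation). Bootstrap
supports resample alignment columns with replacement and count bipartition
recovery; tests and the bundled pipeline use 100 replicates to keep run
times in seconds — the conventional 1000 is a parameter away.

**Group assignment.** Published censuses draw group boundaries on the
figure by eye; the package replaces that with a deterministic rule. For
each query the tree is rooted at the query tip and ancestors are walked
outward; the first ancestor whose subtree contains a labelled anchor
defines the smallest anchor-containing clade, and the query takes the
majority anchor label there (ties: nearest patristic anchor, then
lexicographic). A query whose nearest anchor exceeds
`specific_multiplier × quantile(within-group anchor–anchor patristic
distances, specific_quantile)` is species-specific instead. Defaults:
quantile 0.9, multiplier 2. The multiplier exists because at alignment
lengths around 100–150 the sampling noise of a p-distance is large enough
that a raw 90th-percentile cutoff would misclassify a sizeable fraction of
genuine group members; a factor of two sits far below the distance of a
truly unrelated sequence (≈ 0.95 expected mismatch) while absorbing that
noise. Both knobs are exposed.

**Two stages.** Stage 1 trees all candidates with the R2R3/R1R2R3 anchor
set and labels what clusters with it; the remainder is re-analysed with
the 1R/4R/atypical anchor set; what still clusters with no anchor keeps
the species-specific label. The stage-2 input count always equals the
total minus the stage-1 labelled count.

## 4. Motif discovery (ZOOPS-EM)

**Model.** Each sequence carries zero or one occurrence of a width-W
motif; occurrence probability λ per sequence, uniform positional prior,
position frequency matrix θ, uniform background. The E-step computes
per-position occurrence posteriors; the M-step updates θ with a
pseudocount of `0.01 × background` and λ from the posterior mass. Because
the pseudocount makes the M-step a MAP update, the quantity that is
provably non-decreasing is the penalized log-likelihood (likelihood plus
the Dirichlet log-prior of θ); that is what the trace records and what the
monotonicity tests assert.

**Seeding.** EM on this likelihood has many local optima (phase-shifted
registrations in particular). Starts are therefore seeded the way MEME
seeds them: a pool of candidate windows drawn from the data is scored with
a two-iteration EM burst, and full EM runs only from the best candidates.

**Width selection.** The width grid is 6–50 in steps of 3 — a practical
window within the nominal 2–250 bound, since EM at very large widths is
degenerate on proteins a few hundred residues long. Raw relative entropy
per column cannot select a width: it is flat across sub-widths of a true
motif, and the plug-in estimator of a pure-background column is biased
upward by ≈ `19 / (2·ln2·n)` bits at n sites, which makes background
columns look informative. The selector therefore maximizes the
bias-corrected total `Σ_j (RE_j − bias)`, preferring the widest width
within 2% of the optimum; after the final fit, flanking columns whose
relative entropy stays below `max(2·bias, 0.5)` bits are trimmed, the
model is refit at the trimmed width (recovering occurrences the over-wide
window could not align near sequence ends), and a widen-and-retrim
refinement pads the model with background columns and lets EM re-align, in
case the first registration truncated the motif. Newly exposed flank
columns face a stricter trim threshold (`max(3·bias, 0.75)`) because EM
picks the registration that flatters them. Discovery stops at `max_motifs`
(default 15, the customary cap) or when the best motif's corrected
relative entropy per column falls below 0.3 bits.

**Masking.** Occurrences of found motifs exclude overlapping windows from
all later posteriors, so occurrences of different motifs can never
overlap — an invariant rather than a tendency.

**Known behaviour on random input.** On pure-background sequences the
ZOOPS maximum-likelihood fit does *not* drive λ to zero: EM latches onto
chance similarities with occupancy well above 0.5. What separates real
motifs from noise is the relative entropy per column (≈ 4 bits for a
planted exact motif vs ≈ 1.6–1.9 for the best chance pattern at n = 20)
and the comparison of λ against a planted run, and those are the
discriminators the tests use. Motif boundary estimation is accurate to a
column or two in adversarial cases; the plant-and-recover tests verify
exact-width recovery at the study conditions.

**Logos.** Column information content is `log2(20) − H` (Shannon, bits, no
small-sample correction), letter heights are frequency × IC, and the
stack height of a column equals its IC. Motif matrices are emitted in MEME
minimal text format; logos as simple SVG.

## 5. Gene structure and chromosome distribution

GFF3 is ingested with rtracklayer; one representative mRNA per gene is
kept (longest summed CDS, ties by lexicographic id). Introns are the gaps
between consecutive genomic-sorted exons, so a transcript with n exons
always has n − 1 introns. All coordinates in this package are 1-based
closed intervals — the GFF3 and R/Bioconductor convention — at I/O and
internally, so there is no conversion layer to get wrong. Chromosome
distribution reports per-chromosome counts and a terminal-density
statistic: the fraction of genes whose midpoint falls within
`terminal_fraction` (default 0.25, exposed) of either chromosome end,
quantifying the tendency of large TF families to crowd chromosome ends.

## 6. Orthologs and paralogs

The similarity stage computes exact Smith–Waterman scores for every cross
pair — the sets at this scale (hundreds of proteins) do not need a
heuristic search — and normalizes by the geometric mean of the two
self-scores, giving weights in (0, 1] with identical sequences at exactly
1. The edge threshold defaults to the 99th percentile of a seeded
shuffled-sequence null. Reciprocal best hits require a unique mutual
maximum (any tie disqualifies, conservatively). Markov clustering runs the
classic iteration — column-stochastic matrix with unit self-loops,
expansion (matrix square), inflation (elementwise power 2.0 by default,
1.5–4 exposed), pruning below 1e-5 — until the matrix is stable, and takes
connected components of the limit's support; non-convergence at the
iteration cap returns the current partition with a warning. Ortholog
pairs are RBH pairs whose ends share a cluster; paralog pairs are
same-species edges within a cluster whose weight reaches the cluster's
mean cross-species weight (clusters with no cross-species edge keep all
their within-species edges). A gene may appear in several paralog pairs.
No collinearity constraint is applied: pair linkage, not synteny-block
detection, is the contract.

## 7. Physicochemical profile

Average (not monoisotopic) residue masses with one water (18.01524 Da),
matching the ProtParam convention; Kyte–Doolittle GRAVY (bounded by the
table extremes ±4.5); Guruprasad instability index
`II = (10/L)·Σ DIWV(x_i, x_{i+1})` with the published 20×20 dipeptide
weight table shipped as package data and the conventional "unstable above
40" call. The theoretical pI solves the Henderson–Hasselbalch net charge
for zero by bisection on pH 0–14 to |charge| < 1e-4 (the charge is
strictly decreasing in pH, so the root is unique). Two pKa sets ship: the
Bjellqvist/ExPASy set with residue-specific terminal pKas (default — the
ProtParam convention) and an EMBOSS-style set with fixed termini. Note
that with residue-specific termini, pI is a function of the terminal
residues and not of composition alone. Non-standard residues are rejected
by default; `tolerate_nonstandard` skips them with a warning. All measures
are permutation-invariant except the instability index, which depends on
dipeptide order.

## 8. Relative expression

The Livak 2^−ΔΔCt model with amplification efficiency fixed at 2:
ΔCt pairs target and reference Ct within each (cultivar, stage,
replicate), so per-replicate plate offsets cancel exactly; ΔΔCt compares
condition means against a calibrator condition. The calibrator defaults to
the first developmental stage of the same gene within the same cultivar
(overridable per gene/cultivar), because fold changes across fruit
development are most interpretable against the youngest stage. The
replicate column is the aggregation unit, whether replicates are technical
or biological. The standard error of ΔΔCt combines the replicate standard
errors of both conditions and is propagated through 2^−x by the delta
method, also reported as the asymmetric fold range
[2^−(ΔΔCt+SE), 2^−(ΔΔCt−SE)]. Trend calls over ≥ 3 stages are
"decreasing" when every successive ratio stays within 1 + tolerance
(default 0.05) and the last value is below the first, symmetrically
"increasing", else "none" — matching the qualitative language used to
describe expression during fruit development.

## 9. The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions of the verification suite.

* **Proteome**: proteins of each class carry the requested number of
  complete adjacent copies of a 52-residue repeat consensus, each copy
  independently mutated at a per-position substitution rate (default
  0.05), embedded in uniform random background of 150–400 residues with
  inter-repeat gaps of 1–10 residues; atypical proteins carry a single
  prefix of the consensus covering 40–60% of its length; protein length is
  drawn from the feasible part of the requested range, and geometry that
  cannot fit even the range maximum is an error. The CDS is a fixed-codon
  back-translation plus stop, so CDS length is 3L + 3.
* **Gene models**: uniform non-overlapping placement on the requested
  chromosomes, random strands, requested exon counts with exon spans
  summing to the CDS length — deliberately free of codon-usage, intron
  phase, and chromosome-end density structure (the distribution stage
  measures terminal density; planting it would make that test circular).
* **Anchored families**: each group descends from its own random founder;
  members and anchors are independent mutated copies. Founders are
  unrelated, so between-group distances sit near the random expectation —
  a cleaner separation than real subfamilies exhibit, which is why the
  classification tests demonstrate correctness of the rule, not the
  resolution limit of the method on hard real data.
* **Ct tables**: the 2^−ΔΔCt model run in reverse —
  `Ct_target = Ct_ref + ΔCt_cal − log2(fold) + N(0, σ)` per replicate,
  three replicates per condition, reference Ct around 20 with the same
  replicate noise, five developmental stages (51, 64, 75, 84, 93 days
  after full bloom) and two cultivars in the bundled configuration. At
  σ = 0 the downstream quantification recovers every planted fold exactly;
  at σ > 0 the mean absolute log2 recovery error follows the propagated
  replicate-mean error.

What the generator does not emulate, and what passing tests therefore do
not show about real data: biased amino-acid composition, insertions and
deletions inside repeats, splice variants, paralogous repeat families at
intermediate divergence, non-Gaussian qPCR noise, or amplification
efficiencies different from 2.

**Seeding.** A single integer seed drives everything; each generator draws
from its own named stream (`derive_seed(seed, stream)`, a deterministic
hash), in the documented stream names `proteome`, `gene_models`, `qpcr`,
`seed_alignment`, `groups_<prefix>`, `anchors_stage1`, `anchors_stage2`,
`species_b`. Adding a new generator therefore never perturbs the draws of
existing ones, and regeneration with the same seed is byte-identical.

## 10. Pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order, writes each
stage's artifacts (TSV/JSON/Newick/SVG — text formats throughout) before
the next stage starts, skips stages whose optional inputs are absent with
a warning, aborts with the stage named on failure (retaining earlier
outputs), and finishes with a manifest listing every artifact with an md5
checksum. Identical config + seed reproduces identical checksums; the
bundled golden manifest pins the seed-42 run of the synthetic bundle.
Numeric TSV columns are formatted through a single `%g`-style formatter so
manifests do not depend on printing defaults.

**Problem sizes.** The verification suite runs a 200-protein census at
substitution rate 0.05, a 49-query two-stage classification with 100
bootstrap replicates, motif plant-and-recover with widths 15 and 25 in 30
sequences, 1000 random peptides for the physicochemical oracle, and a
60-protein end-to-end bundle — sizes chosen so the full suite completes in
a few minutes on a single core while every stage still operates well above
its degenerate regime.

## 11. Known limitations

* The PSSM scanner cannot model insertions/deletions within a repeat; a
  repeat interrupted by a long insertion will be found as two partials or
  a truncated match.
* Group assignment transfers anchor labels; it cannot name a group no
  anchor carries, and the species-specific call inherits the distance
  scale of the anchor set.
* Motif widths are estimated to ±0–2 columns in adversarial registrations;
  motif numbering is discovery order, not importance.
* The MCL implementation is dense-matrix; it is meant for desk-scale
  similarity graphs (hundreds to a few thousand nodes), not
  proteome-vs-proteome all-against-all graphs.
* ProtParam values depend on the pKa set; the shipped defaults reproduce
  the ExPASy conventions, and the EMBOSS set is provided for comparison.
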