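---
title: "Reconstructing intron loss histories with intronevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing intron loss histories with intronevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(intronevo)
```

Spliceosomal introns are gained and lost over evolutionary time, and the
pattern of their presence and absence across a gene family carries a
phylogenetic signal of its own. `intronevo` provides a complete toolchain
for this kind of analysis: inferring exon/intron structure from sequence,
building a presence/absence matrix over homologous intron positions,
reconstructing minimum-event histories on a species tree, and examining
the sequence context of losses for mechanistic signatures. This vignette
walks through each stage and explains the conventions and parameter
choices the package makes.

## Coordinates and file formats

All genomic coordinates in `intronevo` are 1-based and closed: an intron
spanning `start = 101, end = 187` includes both endpoints and has length
87. This matches the convention of GFF3 and of most molecular-biology
usage, and avoids the off-by-one traps of half-open systems when
positions are communicated between tools.

Structures can be read from and written to a simple tab-separated
format, and presence/absence matrices round-trip through TSV with genes
as rows and intron slots as columns. Matrix cells take one of three
values: `"P"` (intron present), `"A"` (absent), or `"ND"` (not
determined, for genes where the evidence does not cover that region).
`ND` is carried through every downstream computation as a genuinely
unconstrained state rather than being coerced to either alternative.

## The shipped ABCB1 data set

The package ships a curated matrix of nine intron slots scored in 100
ABCB1 auxin-transporter genes from 80 flowering-plant species, together
with a composite rooted species topology:

```{r}
pm <- abcb1_presence()
tr <- abcb1_tree()
summarize_matrix(pm, rule = "all_copies")$intact_by_clade
```

`summarize_matrix()` supports three rules for calling a *species*
intact when it has several gene copies: `all_copies` (every copy must
retain all nine introns), `any_copy`, and `gene_level` (count genes,
not species). The strict `all_copies` rule is the default because a
species in which any copy has lost introns has demonstrably experienced
loss.

## Inferring structure from sequence

When annotations are not trusted, `infer_introns()` aligns a spliced
transcript (cDNA) back to its genomic sequence with a splice-aware
dynamic program that only opens gaps at canonical `GT...AG` boundaries.
Where several placements of an intron are equivalent — which happens
whenever the junction sequence repeats — the **leftmost** placement is
chosen. This single deterministic convention matters later: it makes
microhomology coordinates reproducible across genes and runs.

## Homology: from positions to slots

Intron positions from many orthologs are projected through a shared
protein or cDNA alignment with `project_introns()` and clustered into
ancestral slots with `cluster_slots()`. Two introns belong to the same
slot only if they fall at the same alignment column *and* the same
phase (0, 1 or 2 — the codon position the intron interrupts); a
position match with a phase mismatch is evidence of independent gain,
not shared ancestry, and is kept separate. Slots are numbered in
alignment order, and `build_matrix()` overlays the clustering onto the
full gene set, filling `ND` where a gene's alignment does not span a
slot.

## Event reconstruction

`dollo_count()` implements Dollo parsimony: the intron is assumed
present at the root and can only be lost, so the minimum history is the
smallest set of branches whose descendant leaves account for every
`"A"`. Events are placed as shallowly as possible — on the stem of the
largest clade that is uniformly absent (with `ND` free to take either
state). `branch_report()` lists each event branch with the leaves below
it:

```{r}
d <- dollo_count(slot_states(pm, 1), tr)
d$n_losses
branch_report(d)
```

`sankoff_min()` is the unconstrained counterpart: a Sankoff dynamic
program over the two states with configurable loss and gain costs and a
free or fixed root. `ND` leaves have cost zero in both states. Ties are
resolved deterministically (a child keeps the parent's state when that
is optimal), so repeated runs give identical reconstructions.
`compare_models()` runs both and reports whether a loss-only history is
as parsimonious as one allowing regain — for the shipped data it is,
for almost every slot, which is the expected behaviour of Dollo
characters.

## Boundary microhomology

Non-homologous end joining tends to leave short direct repeats at
deletion junctions. For each lost-intron junction,
`microhomology()` measures `k5`, the length of exact agreement between
the intron's 5' end and the sequence immediately following the exon
junction, and `k3`, the agreement between the intron's 3' end and the
sequence immediately preceding it; the reported `k = max(k5, k3)`.
Because intron placement itself is ambiguous under junction repeats,
`k` is defined relative to the leftmost placement (see above). The sum
`k5 + k3` is invariant across equivalent placements whenever neither
run is truncated by the end of an available flank, which is what makes
the statistic comparable across genes. `microhomology_survey()`
aggregates per slot; `penultimate_test()` applies Fisher's exact test
to the complementary question of whether exonic bases flanking *lost*
phase-1 introns are relaxed relative to retained ones.

## Motif discovery

`discover_motifs()` fits a one-occurrence-per-sequence EM model of a
fixed-width motif against a background, with multiple random restarts
(each seeded deterministically from the user seed). The model is
regularised with a small pseudocount, so the reported log-likelihood
ratio is a MAP quantity; it is non-decreasing across EM iterations up
to numerical noise, and the trace is returned so this can be checked.
`core_of()` extracts the high-information core of the consensus, and
`empirical_pvalue()` compares the achieved score against scores on
dinucleotide-shuffled copies of the same sequences
(`shuffle_sequences()` preserves dinucleotide counts and terminal
bases). The per-replicate scoring seed is derived from the user seed
plus a fingerprint of the sequence set, so that scoring the identical
set always yields the identical score — a self-comparison therefore
gives an empirical p of exactly 1, as it should.

## Simulation

Every inferential claim in the package can be checked against ground
truth: `simulate_dataset()` generates a random rooted tree, evolves
intron presence down it under per-branch loss (and optional gain)
probabilities, emits genomic and cDNA sequences with canonical splice
sites, and can plant junction microhomology of a chosen length or a
motif at logged positions. The returned object includes the full event
log, so recovered histories, matrices, microhomology values and motif
sites can all be compared exactly to what was generated.

```{r}
td <- simulate_dataset(sim_config(n_leaves = 6, loss_prob = 0.1), seed = 7)
sum(td$events$type == "loss")
```

The scripts under `analysis/` in the source repository run these
checks at scale: Dollo recovery over 1000 simulated histories, planted
microhomology recovery, penultimate-base power curves, and planted
motif recovery against the shuffled null.
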