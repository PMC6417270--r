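---
title: "Methods: motif-grammar mining and classification of fungal peroxygenases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-grammar mining and classification of fungal peroxygenases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upominer)
```

## The problem and the model

Unspecific peroxygenases (UPOs) and chloroperoxidases (CPOs) are
heme-thiolate peroxidases whose catalytic machinery is encoded in a
small, strictly ordered set of sequence motifs. `upominer` treats that
machinery as a grammar and mines proteomes for sequences that spell it
out completely:

* **UPO core**: `PCP` (the central Cys is the proximal heme thiolate;
  Cys36 in AaeUPO numbering) `< S[IL]G < EGD` (distal triad)
  `< SXXRXD < R ··6·· E` — the Arg–Glu acid-base pair with exactly six
  residues strictly between the partners (Arg189/Glu196).
* **CPO core**: `PCP < EHD < E`; the distal His takes over the
  acid-base role, so there is no Arg stabilizer to locate.
* **UPO-like CPO**: the UPO grammar with an `EAD`/`ETD` distal variant
  and/or a seven-residue pair spacing — the signature of a small group
  of sequences annotated as CPOs that pattern with UPOs.

Subfamily structure is read from signature motifs: the NHG family
(`[SN][HY][GN]`, covering the reported variants SHG/NHG/NHN/NYG)
shared by all five subfamilies, plus FXD and a cysteine-pair rule
(subfamily I), RGN/IDG/TXXXXXXR/VPPLPG (II), G[ML]G (III),
CDA/FXXXDG/GAAXXXYE/HXXF (IV) and EDXXH/GXG (V). A molecular-weight
cut at 35 kDa separates the short (Group-I, ~29 kDa average) from the
long (Group-II, ~44 kDa average) mass classes; 35 kDa is the midpoint
of the two reported averages, with the boundary closed on the right.

## Pattern language and scanning

Motif patterns are fixed-length residue-class strings: `[...]` is an
explicit class, `X` a wildcard. There are no quantifiers (`TXXXXXXR`
is eight fixed positions) and no probabilistic models — the motifs are
defined as exact classes, so a PSSM/HMM would add parameters the
definition does not contain. Scanning reports *every* occurrence,
overlaps included; a wildcard matches any letter including the
ambiguity letter `X`, while a sequence `X` never satisfies a
non-wildcard position. Ambiguous input letters (B, Z, J, U, O, stops,
gaps) are normalized to `X` rather than rejected, because fungal gene
models routinely contain them and discarding whole records would bias
the screen.

The grammar engine resolves every choice left-most first (left-most
PCP, then the left-most distal triad preceded by an S[IL]G, the
left-most downstream SXXRXD, and the left-most Arg whose partner Glu
satisfies the spacing), which makes results deterministic and
reproduces the printed AaeUPO anatomy on sequences built to it. The
S[IL]G and SXXRXD requirements are independently relaxable flags
(SXXRXD is reported absent in MroUPO). Both Ile and Leu are accepted
in S[IL]G by default; the three species reported with Leu are not
special-cased. Where the source material places a motif in two
different subfamilies (RGN, G[ML]G, HXXF, and the NHG variant map),
the registry follows the signature table and records the alternative
in the motif's note rather than guessing.

The structural binding-cavity inspection that normally accompanies
such screens is replaced by a sequence-level, report-only descriptor:
`aromatic_context()` counts F/Y/W residues within ±15 positions of the
distal triad midpoint. It never filters candidates and is explicitly
not equivalent to a structure-based check.

## Homology screening statistics

The screen is Smith–Waterman local alignment (BLOSUM62, affine gaps
11/1, a gap of length *k* costing `open + k·ext`) with Karlin–Altschul
E-values `E = K·m·n·exp(−λS)` and the two-tier rule: report at
E ≤ 10, accept at E ≤ 0.01. The analytic λ — the positive root of
`Σ pᵢpⱼ exp(λ sᵢⱼ) = 1` — is implemented and tested
(`calibrate_lambda()`), but it governs *ungapped* alignment only.
Gapped scores follow a Gumbel law whose parameters have no closed
form, so the screening scheme is calibrated empirically
(`calibrate_evalue()`): 600 random sequence pairs of length 200 are
aligned, a Gumbel is fitted by maximum likelihood, and λ and K follow
from its scale and location. Under this calibration the inclusion
threshold behaves as designed: an E ≤ 0.01 acceptance rule yields on
the order of one false positive per hundred searches of shuffled
decoys, which the acceptance script measures directly (500 searches
against 5-decoy databases). The database length entering E is the
summed residue count of the screened proteome.

## Clustering stages

Redundancy removal follows the cd-hit recipe: sort by length
(descending, ties by id), give each record to the first cluster whose
representative shares ≥ 90% identity — identical aligned positions of
the local alignment divided by the *shorter* sequence's length — else
found a new cluster. The word-length-5 prefilter only skips pairs
sharing zero 5-mers (and never fires for sequences shorter than the
word), so it cannot change the partition; the suite asserts the
with/without-prefilter partitions are identical.

The refinement stage is Markov clustering at inflation 1.4 on the
candidates' similarity graph (edges = bit scores at E ≤ 10 by default;
`−log₁₀E` behind a flag). Values the original MCL description leaves
open are fixed here as: self-loop weight = the node's maximum incident
edge weight (1 for isolated nodes), pruning threshold 1e-8,
convergence when the largest absolute entry change falls below 1e-6
within 100 iterations (non-convergence yields a flagged warning, not
an error). Clusters are the connected components of the converged
matrix's non-zero pattern. Only the cluster containing the seed
sequence survives, which is what removes screen survivors that are
similar to something, but not to the query.

## Tree stage

Pog-superfamily membership is a clade property, not a motif class, so
CPO-grammar candidates are placed by tree proximity: Kimura-corrected
distances `d = −ln(1 − p − 0.2p²)` from pairwise local alignments
(saturated pairs with p ≥ 0.85 are capped at 5.0 and flagged),
neighbor joining (exact on additive matrices; taxa sorted before
agglomeration so input order is irrelevant; negative branch estimates
clamped to zero), then nearest-anchor assignment by path length, ties
conservatively to Pog. This is deliberately a scaffold: no
substitution model selection, no bootstrap, no likelihood — the stage
only has to rank a candidate's proximity to an MroUPO-like versus a
classic-CPO anchor, and NJ on corrected distances does that at desk
scale.

## The synthetic study

`generate_proteome()` emulates the statistical situation the pipeline
assumes: a handful of grammar-bearing targets embedded in a large
motif-free background. All planted UPOs descend from one master
scaffold built on the AaeUPO coordinates; every sequence draws its
segment lengths with seed-controlled jitter of up to ±10 positions, so
coordinate-hardcoding bugs surface immediately. Defaults, chosen once:

* 6 planted sequences per subfamily (30 total), 500 uniform-background
  decoys of length 200–500, seed 42 — the default study conditions.
* subfamily templates diverge from the scaffold at rate 0.30, putting
  planted-to-query identities near 60%, inside the identity range
  reported for real mined UPOs against their structure templates
  (26–71%).
* within-subfamily siblings mutate at rate 0.12 (~80–85% pairwise
  identity), below the 90% redundancy cut-off, so each planted target
  is a distinct entity rather than a duplicate to be collapsed.
* motif positions are exempt from mutation; planted backgrounds avoid
  Cys so the subfamily-I cysteine-pair evidence cannot fire
  spuriously; decoys are drawn from the full 20-letter alphabet and
  resampled in the (rare) event they complete a core grammar.

Every planted sequence is verified at generation time to carry its
full signature set and classify into its intended subfamily; the truth
table maps every emitted id to its label and planted coordinates.

What the generator does *not* emulate: real phylogenetic signal,
domain architecture, gene-model errors beyond `X` runs, and
compositional bias of real fungal proteomes (an empirical background
can be supplied, but uniform is the conservative null for motif false
positives). Passing the recovery test therefore demonstrates the
pipeline's internal correctness — screen sensitivity at ~60% identity,
clustering behavior, grammar soundness, classifier discrimination —
not its discovery rate on real genomes, which depends on database
release and homolog divergence.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere except the optional
  BED export (0-based half-open, per BED convention).
* Root finding for the analytic λ runs to 1e-12 absolute bracket
  tolerance; MCL column sums are renormalized after every inflation.
* `X` in molecular weights is counted at a 110 Da mean residue mass
  and flags the value as uncertain rather than failing.
* Sequences shorter than 60 residues (configurable) yield grammar
  class `none`, as do all-background sequences; empty proteomes run to
  completion with empty outputs.
* Classifier ties at the top score and sub-threshold scores yield
  `unassigned` with all five scores reported; the assignment rule
  (arg-max, score ≥ 0.5, ≥ 2 matched signatures) is the package's
  operationalization of "shared signature motifs" and is fully
  configurable.

## Problem sizes in the test suite

The oracle suites run at sizes chosen to finish in minutes on one CPU
while still being exhaustive where exhaustiveness is cheap: motif
scanning against a naive sliding-window matcher on 1000 random
300-mers; alignment scores against a pure enumeration oracle on all
4-letter pairs of lengths ≤ 2 plus seeded length-3 pairs, and against
an independent plain-R Gotoh DP on seeded 4/5-mers (enumerating every
affine local alignment of all ~1.9M ≤5-mer pairs is not tractable, and
adds nothing over the two-route check); MCL against a 1e-12 fixed-point
oracle on 150 seeded graphs of ≤ 6 nodes; neighbor joining against the
generating topology on 200 seeded additive matrices with n ≤ 8; and
the full default synthetic study (531 sequences) end to end.

## Known limitations

* The homology stage is Smith–Waterman with empirical Gumbel
  statistics, not a profile-HMM forward score; sensitivities differ in
  the remote-homology regime even though the two-tier E-value
  semantics are the same.
* Exact-class motifs cannot express position-specific preferences; a
  genuinely degenerate signature would need the registry's class sets
  widened by hand.
* The subfamily-I cysteine-pair rule ("≥ 2 Cys outside PCP") is weak
  evidence and is always flagged as such.
* Pog placement depends on the anchors supplied; without anchors,
  CPO-grammar candidates stay `unassigned` with a `needs-tree` flag.
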