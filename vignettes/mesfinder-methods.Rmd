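---
title: "Methods and design of the MesFinder pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the MesFinder pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

MesFinder screens prokaryotic proteomes for the four families of
folate-independent ("core") methionine synthases — MesA, MesB, MesC and
MesD — together with the related systems a repertoire analysis needs:
MetE, MetH, MetF, split MetE, MesX (DUF1852) and the CoFeSP subunits
AcsC/AcsD of the Wood–Ljungdahl pathway. This vignette explains the
models behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design decisions that were genuinely open.

## Homology scoring and bit thresholds

All family calls rest on pairwise local alignment: Smith–Waterman with
affine gaps under BLOSUM62, a gap of length $L$ costing $11 + L$ matrix
units (the standard BLASTp 11/1 convention). Raw scores $S$ are
converted to bits with the Karlin–Altschul relation

$$\text{bits} = \frac{\lambda S - \ln K}{\ln 2},
\qquad \lambda = 0.267,\; K = 0.041,$$

the standard constants for gapped BLASTp with BLOSUM62 11/1. The
unknown residue X scores 0 against everything. Percent identity follows
the BLAST `pident` convention — identities over aligned columns,
including gap columns — and is rounded to integer percent for
reporting only. For statements about the relatedness of *full-length*
proteins (such as the under-30% separation between the core-synthase
families), `globalPercentIdentity()` uses a global alignment instead:
local identity trims to the best-matching region and systematically
overstates full-length relatedness.

Family membership is a bit threshold against a family reference
sequence. The published operational definitions used profile searches
(phmmer) whose bit scale is close to, but not identical with, the
Smith–Waterman bits produced here; the published values (174 for MesA,
173 for MesB, 38 for MesC, 560 for MesD, 200 for the catalytic
component of split MetE) are therefore **presets**
(`paperThresholds()`), not constants. For any concrete reference set
the thresholds should be, and in this package's own screens are,
recalibrated with `calibrateThreshold()`: the threshold is placed at
the midpoint between the lowest-scoring true member and the
highest-scoring decoy, and calibration errors out if the sets do not
separate. MesD additionally has two published operational definitions
(560 bits / ~72% identity from a reference-proteome screen, versus 390
BLASTp bits / ~55% identity from a genome-neighborhood analysis); both
are exposed as presets and the choice is the caller's.

Two rules refine raw thresholding. First, a protein that clears several
family thresholds is assigned to the family whose query it is most
*identical* to, mirroring how a weak cross-family hit is disregarded
when the protein is far more similar to another characterized query.
Second, the published E-value fallback (E < 0.001) is replaced by a
configurable bit floor, since E-value statistics are out of scope for a
desk-scale tool.

## Functional residues and the zinc site

MetE-family enzymes activate homocysteine through a zinc thiolate; in
E. coli MetE numbering the zinc is coordinated by His641, Cys643,
Glu665 and Cys726, and the substrate is hydrogen-bonded by Ser433,
Glu484 and Asp599. `mapReferenceSites()` maps these positions through
an alignment's column map onto any candidate, and
`classifyZincSite()` applies a compatibility table that encodes exactly
the substitutions discussed for these enzymes and nothing more:
His641 admits no substitute; Cys643 may be His (typical of MesC) or
Tyr (possibly compatible); Glu665 may be Asp (as in the characterized
MesB) but not Gly; Cys726 may be Asn. Any other residue, or an
unaligned position, is incompatible. The overall verdict is *intact*
(all conserved), *broken* (any incompatible or unaligned), else
*compatible*. Families whose reference carries a zinc site enforce a
**site policy**: a candidate above threshold but with a broken verdict
is recorded as a non-enzymatic family-like homolog and excluded from
synthase counts — the treatment given to the Chloroflexales homologs
whose zinc positions read FSHG, YCDQ or YREQ.

One region is deliberately treated leniently: the surroundings of
Glu484 are highly variable in MesB and hard to align, so substrate-site
mapping never affects a verdict; only the four zinc positions do.

## Split MetE

The two domains of MetE are sometimes encoded as two adjacent proteins.
Detection uses two rules, exposed as pure functions so they can be
tested against a rule-table oracle. A *catalytic* candidate needs at
least 200 bits (preset; calibrated in synthetic screens) against the
catalytic-component query and a length of at most 400 residues — the
published threshold was chosen to exclude all members of MesA–D and
MetE, and the length rule separates single-domain proteins from
full-length MetE (at least 676 residues); only the highest-scoring
candidate per genome is kept, ties broken by lexicographic id. A
*folate-binding* candidate must reach the N-domain profile's trusted
cutoff at the same length limit; if it also matches the
catalytic-domain profile, its N-domain score must be strictly higher.
A genome contains split MetE iff both components are found; the two
genes are *not* required to be adjacent, but adjacency is reported.

## Profiles

Where the original analysis used curated profile HMMs (Pfam/TIGRFam),
MesFinder builds gap-free position-specific scoring models from family
alignments: column score for residue $r$ is
$\log_2\!\big(\tfrac{(n_r + \tau b_r)/(n_{\text{eff}} + \tau)}{b_r}\big)$
with pseudocount mass $\tau = 1$ spread over background frequencies
$b_r$, columns with more than 50% gaps dropped, and $-\infty$ floored
at $-10$ bits. Scoring is the best ungapped local window (Kadane's rule
over all diagonals), which is deterministic and invariant to flanking
sequence. Curated-database trusted cutoffs are not reproducible without
those databases; instead each packaged mini-profile records a cutoff
calibrated at build time. Because training sequences score inflated
against an alignment they are part of, the cutoff is set from
*held-out* members drawn across the family's identity range (40–90% to
the seed, the same "~40% identity or above" band that defines
membership in these families), at half the minimum held-out score:
shuffled sequences score an order of magnitude below this, members at
the identity floor comfortably above.

## Multiple alignment and trimming

The progressive aligner is deliberately simple and is not MUSCLE: a
UPGMA guide tree on 3-mer distances, then profile–profile global
alignment up the tree using the pairwise scoring scheme (expected
column-pair score $f_A^\top S f_B$, affine gaps, implemented in C++).
Sequences are ordered lexicographically by id before the guide tree is
computed, so the result is deterministic and independent of input
order. There is no iterative refinement.

The block trimmer honors exactly two parameters — keep columns with a
gap fraction of at most 0.5, then keep only runs of kept columns of
length at least 2 — and records column provenance. It is idempotent.
The additional conserved/flank criteria of the original trimming tool
are intentionally dropped, so column-identical output with that tool is
not claimed.

## Distances, trees

Distances on a trimmed alignment use the mismatch fraction $p$ over
mutually ungapped columns with the Kimura-style protein correction
$d = -\ln(1 - p - p^2/5)$, $p$ capped just below the correction's
singularity ($p \approx 0.854$) with capped pairs flagged. Trees are
Saitou–Nei neighbor joining with Newick output; negative branch lengths
are clamped to zero with the deficit moved to the sibling branch,
preserving path lengths. This stage is a topology-level approximation
standing in for maximum-likelihood tree inference: sufficient to
separate, say, a family from its non-enzymatic sister clade, but branch
lengths are not ML estimates and there is no rate heterogeneity model.

## Repertoire, co-occurrence, operons

The repertoire matrix counts family calls per genome (non-enzymatic
homologs excluded; split MetE counted once per genome when present).
Co-occurrence reports exact counts with the fraction, and an empty
denominator is flagged undefined rather than raised. Sole-synthase
analysis treats {MesA, MesB, MesC, MesD, MetE, MetH, split MetE} as
synthases, with MesD counting only together with MesX by default since
the pair is an obligate unit — a switch exposes the alternative,
because whether MesD alone should count is genuinely open. Genomes
with *no* synthase are listed as `"none"`: exactly the observation that
motivates searching such genomes for new families. "Adjacent" genes
are consecutive on a contig, on the same strand, with an intergenic gap
of at most 300 bp by default: the source analyses never quantify
"adjacent", and consecutive-same-strand-small-gap is the standard
operon heuristic.

## BarSeq fitness

Strain fitness is
$\log_2 \frac{(n_{\text{after}} + 1)/D_{\text{after}}}
             {(n_{\text{before}} + 1)/D_{\text{before}}}$
(pseudocount 1, depths $D$ are total sample counts). Gene fitness is
the weighted mean over strains inserted in the central 10–90% of the
gene, with weight $w = \big(\tfrac{1}{1+n_{\text{before}}} +
\tfrac{1}{1+n_{\text{after}}}\big)^{-1}$ — the inverse of the
approximate variance of a log count ratio, so well-sampled strains
dominate. Samples are normalized by subtracting the median, a
deterministic reading of "most values near zero". The original
pipeline's exact normalization and weighting live in its own software
lineage and numeric equality with it is not claimed; pseudocount and
window are configurable.

## The synthetic-data generator

No accessions of the original screen's inputs are deposited, and a
UniProt-scale screen (hundreds of thousands of proteins) is not a
desk-scale test, so the generator emulates the screen's *statistical
structure* in miniature with known truth:

- A 753-residue MetE-like scaffold carries the canonical functional
  residues at the canonical positions (zinc 641/643/665/726, substrate
  433/484/599). Each core-synthase seed is derived from the scaffold's
  catalytic region through an explicit segment map, placing its sites
  at the positions recorded for the characterized family
  representatives (MesA 216/218/240/301 and 8/59/174, MesB
  214/216/235/311 and 15/69/177, MesC 204/206/225/314 and 11/59/166),
  with short conserved windows (±3 residues) around each site and heavy
  uniform substitution elsewhere. Core seeds are at most 386 residues,
  matching the observed upper bound for these families, and
  inter-family identities are below 30% in the global convention. The
  seeds sit closer to the scaffold (~35–40% local identity) than the
  real families do (<30%), a deliberate trade-off that keeps residue
  mapping well-posed at desk scale; it makes the mapping task easier
  than the real one, which is the main thing passing mapping checks do
  *not* demonstrate about real data.
- Family members are generated from a seed at a controlled target
  identity: substitutions at random non-site positions, drawn in
  proportion to BLOSUM62-positive exchange scores (homolog-like
  substitutions), with zinc residues then written as intact (HCEC) or
  broken (one of FSHG/YCDQ/YREQ). Measured identities land within ±3
  points of the target. Members span 40–90% identity to their seed by
  default — the band that defines family membership.
- Genomes place genes on one contig; operon partners (mesB–acsC–acsD,
  mesD–mesX) are consecutive on one strand with a 50 bp gap, other
  genes 500 bp apart with random strands. Decoys are
  composition-matched shuffles of the seed sequences.
- BarSeq counts: strain abundances after growth are proportional to
  $\text{before} \times 2^{f}$, counts are Poisson at the given depth,
  insertion positions uniform. True gene fitness is 0 for most genes
  with a minority drawn uniformly from $[-5, 1]$ — in a typical
  experiment most genes are neutral, which is also what makes median
  normalization the right centering.

Everything is seeded; the same seed yields byte-identical outputs
(`withSeed()` saves and restores the caller's RNG state).

What the generator does **not** emulate: realistic phylogenetic
sequence evolution (no indel process beyond the fixed segment maps, no
rate variation, no compositional drift), taxonomy, database noise
(fragments, contamination, annotation errors), paralog complexity
beyond simple counts, or profile-HMM search statistics. Passing the
synthetic screen therefore demonstrates the correctness of the
decision rules and the pipeline's plumbing under controlled homology —
not that the published thresholds would reproduce the published hit
lists on a live database snapshot, which are database-version dependent
in any case.

## Problem sizes and numeric choices

The packaged analyses use desk-scale sizes chosen to exercise every
rule: screens of 50 genomes with ~2.5 family members and 10 decoys
each; profile training sets of 6 members; trees of up to 8 taxa for
exactness checks; fitness experiments of 100 genes × 10 strains at
depth 5×10⁵. Alignment tie-breaks are delegated to the deterministic
alignment backend; guide-tree ties are resolved by lexicographic id;
"highest-scoring candidate per genome" ties by lexicographic protein
id. Degenerate inputs fail loudly: empty sequences, all-gap columns,
pairs with no comparable columns, unalignable inputs after trimming,
and non-separating calibration sets are all errors, not silent
defaults.

## Known limitations

- Bit scores are Smith–Waterman bits, comparable to but not identical
  with profile-search bits; published thresholds transfer only after
  calibration.
- The progressive aligner and block trimmer are simplifications; on
  hard alignments (the Glu484 region of MesB, for instance) column
  homology should not be over-interpreted.
- The NJ tree is a distance approximation, not a likelihood tree.
- All packaged reference sequences are synthetic stand-ins carrying the
  documented site geometry; analyses of real proteomes should supply
  real reference sequences for the family queries.
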