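---
title: "Methods: phylogenomic synteny-network analysis of a two-domain gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenomic synteny-network analysis of a two-domain gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`synfam` implements a complete desk-scale workflow for studying a plant
gene family whose members are diagnosed by two conserved protein domains
(the chalcone-synthase-like N-/C-terminal domain architecture):
identification by dual evidence, phylogeny and group assignment,
gene-structure/protein/selection statistics, microsynteny-network
construction with community detection, and phylogenomic profiling. Because
the workflow is meant to be verifiable without multi-gigabyte genome
downloads, every stage is driven by a synthetic-clade simulator that
plants a known family and known evolutionary events, so precision, recall
and recovery can be measured against ground truth.

# The identification model

A gene is a **family** member iff both diagnostic domains are found in its
protein, and **family-like** iff exactly one is found. Domains are located
with position-specific scoring matrices (PSSMs) built from a seed
alignment: per column, residue probabilities are
$(c_{ja} + \lambda)/(n_j + 20\lambda)$ with pseudocount $\lambda = 0.5$,
converted to log-odds bits against a uniform $1/20$ background. The scan
is an ungapped sliding window reporting non-overlapping hits at or above a
cutoff; the default cutoff is $0.6\times$ the consensus self-score of the
matrix, which in simulation separates planted domains from the best random
window by a wide margin (random windows score far below zero on average).
Unknown residues score $-0.5$ bits so runs of `X` cannot accumulate into a
hit.

This replaces profile-HMM construction and search. A full profile HMM
adds position-specific gap states; our simulated domains evolve without
internal indels, and for that regime an ungapped PSSM is an equivalent and
fully specifiable detector. On real proteomes with domain indels the PSSM
scan is more conservative than `hmmsearch` and the cutoff fraction is the
parameter to relax.

Similarity search is exact Smith–Waterman local alignment (affine gaps,
open 11 / extend 1, BLOSUM62), preceded by a shared-5-mer candidate filter
that plays the role of the seeding step in heuristic search tools: pairs
sharing at least 10 distinct 5-mers are aligned, everything else is
skipped. Scoring inside the filter is still the exact alignment, banded
around the main diagonal for near-equal-length pairs (the band exceeds the
length difference by 32, generous for substitution-dominated divergence).
Similarity evidence is recorded as *confirmatory*: the class is decided by
the domain rule alone, and genes whose two evidence trails disagree are
flagged `discordant` for review rather than silently resolved.

# Phylogeny

Family proteins are aligned progressively: a UPGMA guide tree on 3-mer
cosine distances, then profile–profile global alignment with affine gaps
(open 10, extend 0.5) over BLOSUM62, with gap positions carrying zero
weight in the profile columns. Columns are trimmed with a coverage
threshold `gt = 0.8`, a conservation threshold `st = 0.001` (modal-residue
frequency — at this published setting the term is effectively inactive,
which is why the simplification relative to the reference trimmer's more
elaborate similarity score is behaviourally neutral), and a floor
`cons = 60`: at least 60% of the original columns are always retained,
adding dropped columns back by descending coverage (ties: higher
conservation, then left-most).

Trees are built by Saitou–Nei neighbor joining on Kimura-corrected protein
distances $d = -\ln(1 - p - p^2/5)$. Two determinism rules make the result
reproducible and oracle-testable: ties in the $Q$ criterion are broken by
the smallest index pair, and a negative branch length is clamped to zero
with the deficit moved to its sister branch. NJ is exact on additive
matrices, which is the basis of a 200-replicate recovery test on random
4–8-leaf trees. Bootstrap supports resample alignment columns and count
internal bipartitions; rooting places the root at the midpoint of the
outgroup's pendant edge; groups are extracted as the smallest clades
containing user-supplied seed genes, with overlapping clades rejected.
Maximum-likelihood search with model selection was deliberately traded for
NJ: the published analysis used ML, but NJ is deterministic, fast at desk
scale, and its exactness on additive inputs gives an independent oracle —
the package's phylogeny should be read as a verifiable stand-in, not a
re-implementation of the ML pipeline.

# Selection pressure

Within-genome homolog pairs are genes that are reciprocal similarity hits
with global-alignment identity above 50% (identity counted over all
alignment columns; the choice of global identity is exposed in the
configuration). Protein alignments are back-translated to codon
alignments, and Ka/Ks is computed by the Nei–Gojobori (1986) counting
method: per-codon synonymous site fractions from the nine single-base
changes (mutations to stops excluded from the denominator), observed
differences averaged over all minimal mutation pathways excluding
stop-traversing ones, and Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. Pairs with $p \ge 3/4$ are
flagged saturated; pairs with $K_s = 0$ report an undefined ratio. NG86 is
the only estimator on purpose — it is exactly specifiable and is checked
against an exhaustive pathway-enumeration oracle on a thousand random
codon pairs.

# Microsynteny network

All proteins are compared all-vs-all (self-genome comparisons included by
default, switchable) and the five best hits per query per target genome
are kept, ties broken by lexicographic target id. Tandem arrays — maximal
runs of mutually homologous genes at consecutive ranks — collapse to their
best self-scoring member before chaining, and gaps are measured on the
collapsed rank order. Anchors on a chromosome pair are chained by dynamic
programming with the published constraints (minimum block size 3, maximum
rank gap 25, both orientations); the chain score is the anchor count,
which at this scale selects the same chains as an alignment-score-weighted
variant while remaining checkable against exhaustive best-chain
enumeration, which the test suite does on 500 random anchor sets. Maximal
chains are extracted iteratively with a fixed preference order (size, then
same orientation, then lexicographically smallest anchor sequence), so the
block set is a pure function of the anchor set.

Every anchor inside a retained block is an edge of the synteny network;
the family subnetwork keeps exactly the edges whose both endpoints are
family members. Communities are detected by minimizing the two-level map
equation $L(M) = q\,H(Q) + \sum_i p_i^\circlearrowright H(P_i)$ with
degree-proportional visit rates, by greedy node sweeps (ascending id plus
seeded restart orders) alternating with module-merge passes until no move
improves $L$. This replaces the compiled Infomap tool; on graphs small
enough for exhaustive partition search the optimizer attains the global
minimum, which is how it is accepted — equivalence to an oracle, not
label-for-label agreement with an external binary. Clusters below three
nodes are reported but excluded from profiling, matching the published
retention rule.

# Profiling and reporting

Retained clusters are profiled as a cluster × genome count matrix.
Cluster dissimilarity is Jaccard on genome *presence sets* (the published
methods pair the Jaccard measure with species profiling; a count-based
variant can be substituted by passing presence/absence-transformed
profiles), followed by hierarchical clustering with the unsquared
Lance–Williams `ward.D` update — the same update the published analysis
names, and the test suite checks `stats::hclust(method = "ward.D")`
against a hand-rolled Lance–Williams oracle. The overlay step writes
per-edge (leaf, leaf, cluster) connection records and a per-cluster
phylogenetic span (number of distinct groups touched). Headline ratios
(mean copies per carrying genome, percent syntenic members) are rounded
half-up to one decimal to match the published style.

# The simulator: what it emulates, and what it does not

`sim_config()` defines the study conditions. The default clade has 12
genomes on a fixed species tree with root-to-tip lengths around 0.05
substitutions/site, 2 chromosomes × 200 genes, and 6 ancestral family
copies whose proteins are `M + flank(30) + domainN(120) + linker(40) +
domainC(100) + flank(20)` — roughly the ~400-aa two-domain architecture of
the real family. Background genes are random CDSs of 300–1500 codons, long
enough that spurious anchors are rare. Per-branch events are applied in a
fixed order (WGD, tandem, transposition, loss, domain loss, linker indels,
substitutions) so a configuration is exactly reproducible from its seed:

* `wgd_prob = 0.12` per branch — a few WGDs per clade, doubling ploidy;
* `tandem_rate = 0.08`, `transposition_rate = 0.03`, `loss_rate = 0.03`,
  `domain_loss_rate = 0.05` per family gene per branch — a handful of each
  event across the clade, enough to measure recall without overwhelming
  the family;
* substitutions are K2P-like (transition:transversion rate ratio 2),
  uniform across sites, rejected when they create a premature stop;
* purifying selection on family proteins rejects amino-acid changes inside
  intact domains always and elsewhere in the protein with probability
  0.7. The published family evolves under purifying selection
  protein-wide; modeling only the domains as constrained lets one or two
  linker substitutions at tiny synonymous counts push a pair's Ka/Ks
  estimate above 1 purely by counting noise, which is a statement about
  NG86's variance, not about selection. The protein-wide model keeps the
  qualitative property (all defined family ratios below 1) that the
  analysis is meant to exhibit;
* no indels inside domains (keeps the ungapped scan a correct detector);
  in-frame indels are allowed in the linker;
* tandem copies are placed at adjacent rank, matching the tandem-collapse
  rule; transpositions move a family gene to a random position on another
  chromosome and are recorded as ground-truth synteny breaks.

`plant_ploidy_correlation()` draws ploidies and copy counts whose Pearson
correlation targets a requested value (exactly linear at ±1, Gaussian
otherwise), used to verify that a planted correlation of 0.45 — the
magnitude reported for the real family — is recovered within ±0.15 when
averaged over 20 generator seeds at 50 genomes.

The simulator does **not** emulate: realistic codon usage or GC content,
intron sequence evolution (intron lengths are fixed at birth), chromosome
rearrangements other than the listed events, gene families with internal
domain duplications, or annotation noise. Passing tests therefore
demonstrate correctness of the algorithms under substitution-dominated
divergence with clean annotations; they do not certify performance on
fragmented real assemblies.

# Numerical choices and degenerate inputs

* Alignment gap costs: a gap of length $L$ costs `open + L * ext`
  (BLOSUM62 conventions: 11/1 local, 10/0.5 global).
* Saturated Kimura distances (argument of the log ≤ 0) are capped at 5 by
  default for bootstrap robustness; `saturation = "na"` propagates `NaN`,
  which `nj_tree()` rejects naming the offending pair.
* `round_half_up()` nudges by a relative epsilon before flooring so exact
  decimal ties stored inexactly in binary still round up.
* Empty inputs degrade explicitly: empty edge sets give header-only
  files, empty subnetworks give empty labelings, single sequences align
  to themselves, single-leaf dendrograms are a degenerate class.
* The pI bisection runs on [0, 14] to a 1e-3 pH tolerance with a fixed,
  versioned pKa set (`default_pka()`); changing the set is an explicit
  argument, never silent.

# Problem sizes

The shipped tests run the full pipeline on the default 12-genome clade
(~5,000 genes, one CPU, a few minutes), the oracle suites on 500 random
anchor sets, 50 random graphs (≤ 8 nodes, exhaustive partition search),
1,000 random codon pairs and 200 random additive trees, and module tests
on a 4-genome miniature. These sizes were chosen so every oracle is
exhaustive or exactly solvable; the pipeline itself scales to larger
clades linearly in candidate homolog pairs.

# Known limitations

* The PSSM scan has no gap states; domains with internal indels lose
  sensitivity relative to a profile HMM.
* NJ with bootstrap is not a substitute for ML tree inference on real,
  rate-heterogeneous data.
* NG86 underestimates rates at high divergence compared to
  maximum-likelihood codon models; saturated pairs are flagged, not
  rescued.
* One transcript (longest CDS, ties by smallest mRNA id) represents each
  gene; isoform-level structure variation is out of scope.
* The map-equation optimizer is greedy with restarts; on large dense
  graphs it can return a local optimum, as any non-exhaustive community
  detector can.
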