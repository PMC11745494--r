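---
title: "Multi-tissue BCR repertoire analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue BCR repertoire analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribcr)
```

`tribcr` analyses immunoglobulin heavy-chain (IGH) repertoires sampled from
several compartments of the same patient — tumor fragments, draining lymph
nodes (LN), peripheral blood (PBMC), adjacent normal tissue — with cellular
replicates per fragment. This vignette documents the statistical models, the
conventions adopted where the field has no single standard, and what the
packaged synthetic benchmark does and does not establish.

## The unit of analysis

A **clonotype** is the combination of CDR-H3 nucleotide sequence, V gene and
J gene. Isotype is deliberately excluded from the identity key: class
switching changes the constant region while leaving the rearranged junction
intact, so records differing only in constant-region call are merged (counts
summed; the merged isotype is the highest-UMI constituent's, ties broken
IgM > IgG > IgA, a deterministic dominant-expression rule). All quantitation
is UMI-based: a clonotype's frequency is its unique-molecule count over the
sample total, which removes PCR amplification bias but leaves sampling
noise — hence the replicate design.

## Preprocessing rules

Three filters run before any statistics:

* **Cross-sample UMI decontamination.** A UMI tag observed in two or more
  samples with identical or near-identical consensus sequences is treated as
  one physical molecule leaked between libraries. If one sample's read count
  exceeds every other's by strictly more than `ratio` (default 5), the
  molecule is assigned to that sample and removed from the rest; otherwise —
  including a ratio of exactly 5 — it is removed everywhere, because the
  direction of contamination cannot be decided. "Near-identical" is
  quantified as global identity ≥ 0.9 on an equal-length trim (the
  qualitative criterion has no published number; the parameter is exposed).
  For a tag in three or more samples the pairwise rule generalizes
  conservatively: the read-maximal sample survives only if it dominates
  every other involved sample.
* **Singleton exclusion.** Clonotypes supported by a single UMI are removed
  from individual-clonotype analyses (they may be cDNA-synthesis errors) but
  retained for lineage assembly (`keep_singletons = TRUE`), where sample
  size matters more than per-clonotype confidence.
* **Sample-size filter.** Samples retaining 50 or fewer clonotypes are
  flagged excluded — flagged, not dropped, so the decision is auditable.

**Pooling** of replicates or fragments computes each clonotype's pooled
frequency as the arithmetic mean of its per-file frequencies, a clonotype
absent from a file contributing zero. The mean-over-files form gives every
input set equal weight regardless of depth; zeros are required for a common
denominator. Means over a common clonotype universe already sum to one, but
pooled frequencies are renormalized defensively anyway (guarding against
upstream rounding).

## Overlap, clonality, composition

For samples $i, j$ with renormalized frequencies $f$, over shared clonotypes
$k$:

* $F2_{ij} = \sum_{k \in i \cap j} \sqrt{f_{ik} f_{jk}}$ — frequency-weighted
  overlap, 1 iff the frequency vectors coincide (Cauchy–Schwarz).
* $D_{ij} = d_{ij} / (d_i d_j)$ with $d_{ij}$ the shared-clonotype count and
  $d_i, d_j$ the two richnesses — frequency-free overlap.
* $R_{ij}$ — Pearson correlation of $\log_{10}$ frequencies of shared
  clonotypes, requiring at least 3 shared clonotypes (flagged `NA` below
  that). The log-correlation form follows the convention of standard
  repertoire toolkits; it is an assumption, as the quantity has no unique
  published formula.

Overlap metrics grow with richness, so comparisons are normalized to the
same number of top clonotypes per isotype from each sample (default
N = 109). When a sample holds fewer, all are used and the result carries a
shortfall flag rather than excluding the sample.

**Clonality** is $1 - H/\ln d$ (one minus the normalized Shannon–Wiener
index; natural log, which cancels in the normalization): 0 for a perfectly
even repertoire, approaching 1 under single-clone dominance. A
one-clonotype repertoire is defined as clonality 1 (maximal dominance) —
the limit $d \to 1$ is otherwise 0/0.

## CDR-H3 physicochemistry

Descriptors are computed on the five central amino acids of each CDR-H3 (a
window centred by `start = floor((len - w)/2)`, 0-based — the left-biased
convention of common toolkits; shorter sequences are used whole and
flagged) for the top 100 most frequent clonotypes, then averaged
*unweighted* across clonotypes — the statistic is a property of the
clonotype set, not of expression.

* **charge** = #(K, R) − #(D, E); histidine excluded by the pH-7 net-charge
  convention (configurable).
* **hydropathy** = mean Kyte–Doolittle index.
* **strength** (predicted interaction strength) = count of strongly
  interacting residues {F, I, L, M, V, W, Y}; the set ships as an
  overridable resource because no closed formula exists for this
  toolkit-defined quantity.
* **kf1–kf10** = mean Kidera factors. The packaged table is the published
  standardized scale; each factor has mean ≈ 0 and population variance ≈ 1
  over the 20 residues, and that invariant is asserted in the tests to
  guard against transcription errors (the n−1 sample variance is 20/19 of
  it, which is why the check uses the population form).

Group contrasts use two-sided t or Mann–Whitney tests per descriptor with
Bonferroni or Bonferroni–Holm correction.

## Clonal lineages and hypermutation phylogeny

Clonotypes are partitioned by V gene, J gene and CDR-H3 length (the D
segment is ignored — its germline call is too short and too mutated to be
reliable), then clustered by **single linkage** on normalized Hamming
distance between equal-length junctions. Equal lengths make alignment
unnecessary. The distance threshold is detected per dataset as the deepest
local minimum between the two largest modes of the kernel-density estimate
of the distance-to-nearest distribution (Silverman's rule-of-thumb
bandwidth; minimum searched in (0.05, 0.5)). The low mode collects
hypermutation neighbours, the high mode unrelated junctions; the valley
typically sits at 15–20% distance (80–85% identity). With fewer than 20
distances, a unimodal estimate, or no admissible minimum, a conservative
fallback of 0.15 is used and flagged. Single-linkage clustering at
threshold $t$ is exactly the connected components of the
distance-≤-$t$ graph; the test suite verifies this equivalence against an
independent graph oracle.

Each lineage of five or more distinct junctions gets a rooted tree:
neighbour joining on pairwise normalized Hamming distances over members
plus a **germline outgroup** — the conjugate of the germline V 3' end and
J 5' start across the junction, with the unknowable D/N middle masked as
`N` and excluded from every distance involving the outgroup. Germline
coverage at each end is chosen by the best-scoring ungapped overlap
(matches minus mismatches, ties to the longer overlap, minimum 3 nt)
against the lineage consensus. Members are ordered lexicographically before
tree construction and negative NJ branch lengths are clamped to zero, so
trees are deterministic and order-independent; root distances are rounded
at 1e-10 so that genuinely equal depths tie in the ranks. Two-member
lineages use the exact three-taxon solution. Neighbour joining replaces
maximum-likelihood (GTR+GAMMA) inference deliberately: it is deterministic,
dependency-free and desk-scale, and the downstream statistics consume only
root-distance *ranks* and pooled substitution counts, which are far less
sensitive to branch-length model than the trees themselves. Fidelity to ML
topologies is not claimed.

Mutation loads are Hamming distances to the outgroup over germline-covered
positions (a lower bound on true loads, since the masked middle is
excluded); a precomputed `germline_mutations` column, when present, is used
verbatim. **dN/dS** uses Nei–Gojobori counting of each member against the
outgroup/MRCA, pooled over the lineage: synonymous site fractions per codon,
substitution classification averaged over all orderings of multi-site codon
changes, stop codons treated as a 21st residue state, and
$dN/dS = (N_d/N)/(S_d/S)$ with no pseudocounts — zero synonymous
substitutions yield a flagged undefined result rather than an arbitrary
number. Pooling against the MRCA (rather than per-branch counting) matches
the resolution of short junction-only data.

## Triangle tissue distribution

Each clonal group becomes one barycentric point: the shares of its member
clonotypes attributed to each of three compartments. A clonotype observed
in $k$ compartments contributes one count to each — occurrence-level
counting is the only reading under which coordinates sum to one. Dominant
isotype requires a strictly >60% share, else "mixed". Equal contribution of
the three compartments is tested per group by chi-squared goodness of fit
against expected counts size/3 (df = 2; groups under 6 members are flagged
low-count since expected cells fall below 2), and overall by the same test
on summed counts; the plotted center is the unweighted mean of the
coordinates, so small and large groups count equally. Optional
isotype-usage normalization downsamples each compartment to equal top-N
clonotypes per isotype first, removing quantitative isotype bias between
compartments.

## Expanded-clonotype detection

Raw per-sample UMI counts are distorted by sampling bias (tumor fragments
of unequal size), so testing uses **pseudo-counts**: clonotype frequency in
the normalized sample times the total number of unique UMIs over all sample
groups, rounded to integers. Groups are compared per clonotype by a
two-sided exact test of the group-A sum conditional on the clonotype's
total, against the library-size-proportional binomial null; p-values sum
all outcomes no more likely than the observed one. Calls use BH-adjusted
FDR < 0.05 and logFC > 0 (base 2, prior count 0.5 to stabilize zeros, group
means put on a common library scale first).

One consequence of the pseudo-count transform deserves emphasis: it
multiplies every count by roughly the number of samples, inflating apparent
evidence about four-fold in a four-sample comparison. A plain binomial test
on such counts is anti-conservative; this is precisely why the original
workflow routed the counts through a dispersion-estimating differential
abundance framework. `tribcr`'s default (`dispersion = "auto"`) estimates
the variance-to-mean ratio (quasi-dispersion) from the replicates — under a
scaled-Poisson model this ratio *is* the inflation factor — and deflates
counts to their effective Poisson scale before testing. The simulations in
the test suite show this calibrates the null while retaining essentially
full sensitivity for 8-fold expansions at two replicates per group.
Tag-wise dispersion estimation is out of reach at two replicates; a fixed
numeric `dispersion` instead selects a beta-binomial with
negative-binomial-style overdispersion for users with external estimates.

## The synthetic benchmark

`simulate_repertoires()` emulates the study design the analyses assume: per
patient, founder clones with junctions built as germline V-end, random
stop-free N-insertions and germline J-start (from a packaged *synthetic*
pseudo-germline of 10 V and 10 J alleles — a stand-in for an IMGT database,
sufficient for junction-level outgroup work); clonal lineages grown as
mutation trees (each new member mutates off a random existing member with
Poisson(rate × length), minimum 1, substitutions, never creating stops);
pairwise tissue sharing (defaults: tum–LN 0.30, tum–PBMC 0.05, LN–PBMC
0.10 — ordered so that tumor repertoires resemble their draining LNs far
more than blood); per-tissue isotype mixtures (PBMC IgA > IgG > IgM, the
ordering typical of circulating antibody-secreting cells; tumor shifted
toward IgG/IgA); log-normal per-clone expression (σ = 1.5, emulating plasma-cell
dominance up to hundreds-fold); log-normal per-fragment jitter (σ = 1,
shared by a fragment's replicates — this is what makes replicate pairs
agree more than fragment pairs); three tumor fragments, one LN and one PBMC
compartment, two cellular replicates each, multinomial UMI sampling per
replicate; optional planted expansions and planted cross-sample UMI
contamination. Every planted feature is recorded in a ground-truth ledger.

What the generator does **not** emulate: AID hotspot motifs and
transition/transversion bias in SHM, class-switch ordering along lineages,
V-region sequence outside the junction (short-read emulation), germline
allele polymorphism, and clone-size power laws beyond the log-normal.
Passing tests therefore demonstrate correctness of the implementations and
recoverability of planted structure under the stated model — not
performance guarantees on real repertoires.

Default problem sizes in the tests and acceptance script (250–1,000 clones,
800–3,000 UMIs per sample, 50–100 simulation seeds) are chosen as the
smallest scales at which the stochastic properties stabilize; the whole
suite runs in a few minutes on one CPU.

## Numerical conventions and edge cases

* Sequence coordinates are 0-based half-open internally; all identity
  computations on equal-length strings.
* Single-linkage cut uses threshold + 1e-9 so that distances exactly at the
  threshold merge (identity "above a certain threshold" is inclusive for
  the identity value, and junction distances are rational multiples of
  1/length).
* `detect_threshold` is shift-consistent (moving both modes by δ moves the
  valley by ≈ δ); this is tested.
* Ratio comparison in decontamination is strict (">5×"), so a tie falls to
  the eliminate-both branch.
* Frequencies renormalize after every filter, subset or pool; empty
  repertoires raise typed errors instead of NaN.
* Unknown isotypes are kept in repertoires but excluded from per-isotype
  denominators.
* The pipeline writes TSV stage outputs plus a JSON manifest of parameters
  and output checksums; a rerun with the same configuration is
  byte-identical, which the tests assert.

## Known limitations

* NJ trees are a stated approximation; branch lengths are normalized
  Hamming distances, not substitution-model corrected.
* Junction-only mutation counts undercount SHM relative to full V-region
  data; `germline_mutations` passthrough exists for pipelines that align
  the V region upstream.
* The quasi-dispersion correction assumes the dominant overdispersion is a
  common scale factor; strongly clonotype-specific biological variability
  between replicates would require the beta-binomial path with an external
  estimate.
* The D/N junction middle is masked in outgroup distances, so lineages
  whose variation is concentrated there carry less rooting information.
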