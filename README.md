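# tribcr — multi-tissue B-cell receptor repertoire analysis

B cells infiltrating a tumor may be locally activated, hypermutating and
selected, or may simply recirculate from the periphery. Distinguishing these
regimes from sequencing data requires comparing the immunoglobulin
heavy-chain (IGH) repertoires of the tumor, its draining lymph nodes (LN)
and peripheral blood (PBMC) of the same patient — clonal composition,
isotype usage, CDR-H3 physicochemistry, clonal-lineage structure and
hypermutation phylogeny — under careful control of UMI-level contamination
and cell-sampling noise. `tribcr` implements that analysis for AIRR-style
clonotype tables, together with a synthetic multi-tissue repertoire
generator that makes every stage testable without patient data.

For sample pair *i, j* with clonotype frequencies *f* the core statistics
are:

- overlap **F2** = Σ<sub>k∈i∩j</sub> √(f<sub>ik</sub>·f<sub>jk</sub>)
  (frequency-weighted), **D** = d<sub>ij</sub>/(d<sub>i</sub>·d<sub>j</sub>)
  (frequency-free), and **R**, the Pearson correlation of log10 frequencies
  of shared clonotypes — computed on equal top-N-per-isotype subsets
  (N = 109 by default);
- **clonality** = 1 − H/ln d (one minus the normalized Shannon–Wiener
  index);
- CDR-H3 **charge, hydropathy, interaction strength and Kidera factors
  kf1–kf9** over the five central residues of the top-100 clonotypes;
- **clonal lineages** by V/J/CDR-H3-length partition plus single-linkage
  clustering at an automatic distance-to-nearest threshold, with
  germline-outgroup-rooted trees, distance-to-root ranks and pooled
  Nei–Gojobori **dN/dS**;
- **triangle (barycentric) statistics** of clonal-group spread across three
  compartments with chi-squared equal-contribution tests;
- **expanded-clonotype detection** from UMI-normalized pseudo-counts with a
  replicate-calibrated exact test (FDR < 0.05, logFC > 0).

See `vignettes/methods.Rmd` for the models, conventions and limitations.

## Worked example

```r
library(tribcr)

sim  <- simulate_repertoires(sim_config(seed = 42), emit_umi = FALSE)
reps <- repertoires_from_airr(sim$airr)
reps <- lapply(reps, apply_filters)                     # singletons out, <=50-clonotype samples flagged
reps <- reps[!vapply(reps, is_excluded, logical(1))]
tiss <- vapply(reps, function(r) r$metadata$tissue, character(1))
pool <- function(t) pool_repertoires(reps[tiss == t], warn_context = FALSE)
tum <- pool("tum"); ln <- pool("LN"); pbmc <- pool("PBMC")

f2(tum, ln)    # 0.3039
f2(tum, pbmc)  # 0.1027
```

The tumor repertoire overlaps its draining LN three-fold more strongly than
blood — the configured tissue-sharing structure (tum–LN 0.30 vs tum–PBMC
0.05) recovered at the repertoire level.

```r
clonality(tum)                                  # 0.2036
clonality(pbmc)                                 # 0.3171
round(isotype_fractions(pbmc, weight = "clonotype"), 3)
#   IgM   IgG   IgA
# 0.259 0.279 0.463

lin <- build_lineages(pool_repertoires(reps, warn_context = FALSE),
                      threshold = "auto")
attr(lin, "threshold_used")                     # 0.163 (auto-detected valley)
ls <- lineage_summary(lin)
sum(ls$size >= 5)                               # 24 lineages large enough for trees
dn <- lineage_dnds(lin, min_size = 5)
median(dn$dnds[dn$defined])                     # 0.864
```

The automatically detected clustering threshold lands in the expected
80–85% identity band (distance 0.163), and lineage-pooled dN/dS sits below
one, as expected for junction sequences evolving without positive
selection pressure in the simulation.

The whole chain — decontamination, filtering, pooling, overlap, diversity,
physicochemistry, lineages, triangle statistics, expansion testing — runs
from one declarative configuration:

```r
run_pipeline(list(seed = 1, out_dir = "my_run"))   # TSV per stage + manifest.json
```

A thin CLI over the same functions ships in `inst/scripts/repseq.R`
(`simulate` and `run` subcommands).

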