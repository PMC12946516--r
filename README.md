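# homeobias

Homoeolog-resolved expression and chromatin bias analysis for
allotetraploid genomes.

Allopolyploid plants — here a two-subgenome (M/U) tetraploid of the wheat
family — carry most genes as homoeologous pairs (*dyads*), one copy per
subgenome. This package implements, as tested and reusable R functions,
the analyses needed to ask how expression and active chromatin are
partitioned within dyads and whether structural rearrangements (SRAs)
between the subgenomes disturb that partition. It is aimed at plant
comparative genomicists who have gene annotation, alignment hit tables,
TPM matrices and ChIP-seq fold-enrichment tracks in standard formats and
want the dyad-level statistics without re-deriving them.

## What it computes

- **Dyad identification** by iterative reciprocal best hits: filter hits
  (target coverage ≥ 90%, identity ≥ 90%, e ≤ 1e−5), take best hits both
  ways, keep mutual pairs, remove them, repeat until no new pair appears.
- **Expression bias** per dyad: HEB = log2(TPM_M/TPM_U) (pseudocount
  1e−6 for silenced copies); normTPM_M = TPM_M/(TPM_M+TPM_U); dominance
  as the nearest of (0.5, 0.5), (1, 0), (0, 1) in Euclidean distance
  (boundary at normTPM_M = 0.75, i.e. HEB = log2 3). CV classes
  (conserved < 0.35 < intermediate < 1 < highly variable) describe
  per-gene variability across tissues.
- **Dyad dynamics**: per-tissue Euclidean deviation of the normalised
  ratio from the global ratio, averaged into the CMD; CMD deciles give
  stable (bottom 20%), intermediate, dynamic (top 20%) classes.
- **Chromatin bias**: area under the H3K4me3 fold-enrichment curve over
  each gene ± 2 kb; HPHB = log2((Area_M+1e−6)/(Area_U+1e−6)); peak
  presence within ±500 bp of the coding start.
- **SRA comparisons**: seven metrics tested between rearranged and
  non-rearranged genes/dyads (Kruskal–Wallis, rank-sum, chi-square;
  BH-adjusted), globally and per rearrangement block.
- **Window utilities**: 50 Mb depth windows with median normalisation for
  assigning chromosomes to disomic addition lines, and 1 Mb CENH3 windows
  with prominence-based peak calling for centromere midpoints.
- **A synthetic allotetraploid generator** (annotation, hits, expression,
  chromatin, coverage, plus a truth table) so the whole pipeline runs and
  validates end to end without any external data.

## Worked example

Run the full synthetic study — simulate, write files, read them back,
pair, classify, compare, window analyses — from one seed:

```r
library(homeobias)
cfg <- sim_config(seed = 42)          # 2000 dyads, 7 tissues by default
run <- run_all(cfg, outdir = "demo_run")

nrow(run$pairing$dyads)               # 1958 dyads recovered
table(run$expression$summary$dominance)
#   balanced M_dominant U_dominant
#        973        271        289
table(run$dynamics$dynamics_class)
#      dynamic intermediate       stable
#          306          920          307
run$compare_global[, c("metric", "n_control", "n_rearranged", "p_adj", "stars")]
#           metric n_control n_rearranged    p_adj stars
# 1            HEB       784          329 3.99e-01    ns
# 2            TPM      3155          761 6.64e-16    **
# 3           HPHB       784          329 3.99e-01    ns
# 4 H3K4me3_summit      3155          761 6.64e-16    **
# 5 prop_expressed      3155          761 1.16e-12    **
# 6            DCB       784          329 1.48e-01    ns
# 7 H3K4me3_status      3155          761 2.69e-08    **
```

Reading the table: the planted rearrangement halves expression of both
homoeologs of affected dyads and adds extra silencing, so the *absolute*
metrics (TPM, expressed proportion, summit FE, peak status) drop
significantly in rearranged regions, while the *relative* within-dyad
metrics (HEB, HPHB) stay flat — the signature of dosage-balanced
perturbation. The window stage assigns all 13 addition lines to their
true chromosome and finds the planted double centromere signal on
chromosome 5M (`run$centromeres$n_peaks[["5M"]]` is 2).

Result tables land in `demo_run/results/`, the simulated input files in
`demo_run/data/`, and `demo_run/manifest.json` records the seed,
parameters and result checksums; re-running with the same seed
reproduces every file byte for byte.

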