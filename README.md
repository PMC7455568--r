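# difatten

Selection of genes whose treatment response is attenuated by a gene
knockout, from bulk RNA-seq TPM matrices with **one pooled sample per
design cell** — the setting of surgical osteoarthritis (DMM vs. sham)
studies in wild-type and knockout mice profiled at 2 and 4 weeks, where
cartilage pooling leaves no replicates and standard dispersion-based
differential-expression tools do not apply.

## The method

For each gene, genotype *g* ∈ {WT, KO} and week *w* ∈ {2, 4}, with TPM
values *E* and pseudocount ε (default 1):

    L_g(w)  = log2( (E_DMM + ε) / (E_sham + ε) )
    DIF(w)  = L_KO(w) − L_WT(w)

A negative DIF marks transcriptional suppression of the DMM response in
the knockout. Over the universe of expressed genes (TPM > 1 in ≥ 1
sample), a gene is selected at week *w* when (strict inequalities)

1. `L_KO(w) < 0`
2. `L_WT(w) > 0`
3. `DIF(w) < DIF_25%(w)` — the lower quartile of DIF over the universe

and is a **common gene** when all three hold at both weeks. The two-week
overlap is tested with an upper-tail hypergeometric p-value against the
filtered universe, and the common set is scored against a GMT gene-set
collection (after mouse→human ortholog translation) by hypergeometric
tests with Benjamini–Hochberg FDR, each set scored as −log10(q).

A seeded synthetic-data generator (`simulate_study()`) plants
ground-truth attenuated genes in a study-shaped 8-sample matrix so the
whole pipeline is testable without any download.

## Worked example

```r
library(difatten)

cfg <- simulation_config(seed = 7)   # 2000 genes, 8 samples, 5% attenuated
sim <- simulate_study(cfg)

filt      <- filter_expressed(sim$matrix)        # TPM > 1 in >= 1 sample
contrasts <- log2_contrast(filt, pseudocount = 1)
difs      <- dif_scores(contrasts)
sel2      <- select_week(contrasts, difs, 2)
sel4      <- select_week(contrasts, difs, 4)
common    <- common_genes(sel2, sel4)

c(universe = nrow(filt), week2 = length(sel2),
  week4 = length(sel4), common = length(common))
#> universe    week2    week4   common
#>     1800      330      344      135

overlap_pvalue(length(common), length(sel2), length(sel4), nrow(filt))
#> [1] 3.255016e-25

difs
#> DIF table: 1800 genes x 2 week(s); quartile scope: per_week
#>   week 2: dif_q25 = -0.3702
#>   week 4: dif_q25 = -0.3733
```

135 genes pass all four requirements; the overlap between the two weekly
selections is far beyond chance. Enrichment against a fixture collection
with one set planted from the attenuated class:

```r
fx         <- make_fixture_collections(sim$truth, n_sets = 5,
                                       set_size = 50, seed = 7)
query      <- map_orthologs(common, fx$orthologs)
background <- map_orthologs(rownames(filt), fx$orthologs)
head(enrich_collection(query, fx$collection, background), 3)
#>                  set  k  K   n    N            p            q       score
#> 1 PLANTED_ATTENUATED 38 50 135 1800 5.166475e-35 2.583237e-34 33.58783567
#> 2          RANDOM_04  6 44 135 1800 1.064156e-01 2.660390e-01  0.57505468
#> 3          RANDOM_01  2 41 135 1800 8.263902e-01 8.641204e-01  0.06342572
```

The planted set ranks first (score 33.6); random sets sit near zero.

`run_pipeline()` wires all stages end to end, writes
`selected_genes.tsv`, `overlap.tsv`, `enrichment.tsv`,
`node_attributes.tsv` (gene/DIF pairs for network software) and a JSON
run manifest. The same pipeline is available from a shell:

```sh
Rscript inst/cli/difatten.R simulate --out sim --n-genes 2000 --seed 7
Rscript inst/cli/difatten.R run --matrix sim/matrix.tsv --samples sim/samples.tsv \
    --gmt sim/sets.gmt --orthologs sim/orthologs.tsv --out results
```

Exit codes: 0 success, 2 input/format error, 3 computation error.

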