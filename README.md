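# il17path

Comparative transcriptomics of psoriasis and cutaneous squamous cell
carcinoma (cSCC), centred on the IL-17 signalling pathway. The package is
aimed at computational biologists who want a tested, self-contained
implementation of the full workflow: differential-expression calling with
dual threshold regimes, cross-dataset biomarker intersection, local
gene-set over-representation analysis, and a dynamic reaction-network
model of the IL-17 signalling sub-pathway with local sensitivity analysis
of its biological-process outputs.

## What it computes

**Differential expression.** For each gene in a two-group contrast the
package fits the two-sample linear model and moderates the variance by
empirical Bayes. With pooled within-group variance `s2_g` on `df` degrees
of freedom, the prior `(d0, s0^2)` is estimated by moment matching on
`log s2_g`, and each gene is tested with

    s2_tilde_g = (d0 * s0^2 + df * s2_g) / (d0 + df)
    t_g = log2FC_g / sqrt(s2_tilde_g * (1/n_a + 1/n_b)),   t_g ~ t(d0 + df)

A gene is called differentially expressed only when it crosses both the
p-value and the fold-change threshold of its regime: *stringent*
(`p < 0.005`, `|log2FC| > 1`) for disease vs normal contrasts, *relaxed*
(`p < 0.05`, `|log2FC| > 0.5`) for subtype vs subtype and non-lesional vs
normal contrasts. Both inequalities are strict.

**Over-representation.** DEG sets are tested against a GMT collection
with the one-sided hypergeometric upper tail
`p = sum_{k >= x} C(K,k) C(N-K,n-k) / C(N,n)`, conditioned on the genes
actually measured; pathways with `p <= 0.05` in every dataset form the
common-pathway set.

**Pathway dynamics.** The IL-17 sub-pathway is shipped as two curated
reaction networks (psoriasis and cSCC): role-tagged species (ligands,
receptor/adaptor complexes, kinases, transcription factors, effector
families, inhibitors, and three terminal biological processes — autoimmune
pathology, neutrophil recruitment, immunity to extracellular pathogens)
joined by mass-action conversion, inhibitor neutralisation, enzymatic
activation, cooperative induction and first-order turnover reactions.
Differentially expressed species start at their average disease
expression (shipped table), other genes at 0.5, processes at 0. The ODE
system is integrated with a stiff-capable solver, and process outputs are
interrogated by fully normalised local sensitivities
`n(t) = (dY/dX0) * X0 / Y(t)` summarised as `max |n(t)|`, with inputs
exceeding 1.5 classified as high-sensitivity.

## Worked example

```r
library(il17path)

## synthetic dataset: 2000 genes, 5 lesional vs 5 normal, 5% planted DEGs
sp <- synth_spec(2000, c(lesional = 5, normal = 5), deg_fraction = 0.05,
                 effect_size = 2, sigma = 0.5, seed = 1)
d <- generate_microarray(sp)
res <- run_de(d$matrix, contrast_spec("lesional", "normal", "stringent"))
sum(res$is_deg)
#> [1] 103
head(res[order(res$p), c("gene", "log2fc", "t_mod", "p")], 3)
#>      gene log2fc t_mod        p
#> 66 G00066   2.55  8.30 8.79e-14
#> 75 G00075  -2.52 -8.12 2.40e-13
#> 10 G00010   2.39  7.75 1.87e-12
```

All 100 planted genes are among the 103 calls; the three extra calls are
the expected price of the raw-p regime. The seeded psoriasis pathway
model then reproduces the characteristic process kinetics:

```r
mod <- il17_model("psoriasis")
peak(simulate_model(mod), "autoimmune_pathology")
#> t_peak  value
#>  9.200 28.045

S <- compute_sensitivities(mod)
round(S["autoimmune_pathology",
        c("MAPKs", "AP1", "chemokines", "tissue_remodeling", "antimicrobial")], 2)
#>            MAPKs               AP1        chemokines tissue_remodeling
#>             1.72              1.97              1.82              2.44
#>    antimicrobial
#>             0.02
```

The three process trajectories coincide, plateauing near 28 around 9.2
time units in psoriasis (the cSCC model climbs to about 21 by 10 time
units), and the high-sensitivity classification (`classify_high(S)`,
threshold 1.5) flags the MAPK family, AP-1, chemokines and
tissue-remodelling genes in psoriasis, and MAPKs, AP-1 and TNF in cSCC.

The full demo workflow — synthetic datasets, per-dataset DE, DEG
intersection, enrichment, common pathway, model simulation and
sensitivity — runs from one call and writes all artifacts plus a
checksummed manifest:

```r
run_pipeline(pipeline_config("artifacts", seed = 1))
```

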