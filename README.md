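# barcodiv

Biodiversity assessment from COI DNA-barcode surveys of hyperdiverse
arthropod communities — mites being the motivating case. Dense arthropod
groups defeat morphology-based surveys: most specimens are immature,
cryptic, or belong to undescribed species. Barcode surveys sidestep this
by sequencing the ~648-bp COI fragment from thousands of specimens and
treating sequence clusters (MOTUs — molecular operational taxonomic
units) as species proxies. `barcodiv` implements the full analytical
chain such a survey needs, for ecologists who have a FASTA file of
barcodes and a specimen metadata table, and want defensible richness and
community-structure numbers out the other end.

## What it computes

**Quality grading.** Two grades with fixed boundary semantics: a
reference grade (length > 500 bp, ambiguous fraction < 1%) and an
analysis grade (length ≥ 300 bp, < 1%). Per-order sequencing success is
summarized and tested for homogeneity with a Pearson χ² on the
order × {recovered, failed} table.

**MOTU delineation.** Pairwise absolute nucleotide differences (ends-free
alignment; substitutions plus internal gap columns; ambiguous columns
excluded), then single-linkage clustering at an absolute threshold
*t* = 15 changes (≈ 2.3% of a full barcode): MOTUs are the connected
components of the graph joining pairs with *d* ≤ *t*.

**Richness.** Specimen-based accumulation curves (random permutations,
default 1000 iterations) with a closed-form hypergeometric rarefaction
oracle

&nbsp;&nbsp;&nbsp;&nbsp;E[S(n)] = S_obs − Σᵢ C(N−Nᵢ, n)/C(N, n),

terminal-slope completeness calls (slope > 0.1 very undersampled,
\> 0.01 modestly undersampled), and Chao1 richness with standard errors:

&nbsp;&nbsp;&nbsp;&nbsp;Ŝ_classic = S_obs + f₁²/(2f₂),&nbsp;&nbsp;
Ŝ_bc = S_obs + f₁(f₁−1)/(2(f₂+1)),

where f₁, f₂ are singleton and doubleton counts (variances from the
Chao 1987 family). Families are analysed separately when they exceed
100 specimens or 10 MOTUs, the rest pooled per order; checklist and
augmented-sampling comparisons report half-up integer percent changes.

**Community structure.** Site- or substrate-level abundance matrices,
Hellinger transformation y′ = √(y/rowsum), Bray-Curtis dissimilarity
d = Σ|u−v|/Σ(u+v), complete-linkage dendrograms (written as Newick), and
ANOSIM: R = (r̄_between − r̄_within)/(M/2) on mid-ranked dissimilarities
with a permutation p-value that counts the observed labelling.

**Synthetic communities.** A generator with known ground truth: species
references separated by ≥ 30 changes, conspecific specimens within ≤ 5,
log-series abundances, forested/non-forested site turnover, per-order
sequencing dropout, and QC artifacts. Under the identifiability
condition (2·max_intra ≤ t < min_inter − 2·max_intra) MOTUs recover true
species exactly, which anchors the end-to-end tests.

## Worked example

```r
library(barcodiv)

cfg    <- simulation_config(n_species = 60, seed = 11)
pool   <- generate_species_pool(cfg)
survey <- sample_specimens(pool)
survey
#> Synthetic barcode survey: 349 specimens drawn, 256 barcodes recovered
#>   species pool: 60 | sites: 10 | substrates: 8
#>   artifacts: 2 truncated, 3 with ambiguity runs

fit <- barcode_survey(survey$sequences, survey$metadata,
                      iterations = 200, permutations = 999,
                      min_specimens = 20, min_motus = 5, seed = 99)
fit
#> DNA-barcode biodiversity survey
#>   sequencing success: 256 / 349 specimens (73.4%)
#>   analysis-grade barcodes: 253 (reference-grade: 251)
#>   MOTUs at threshold 15: 53 from 253 specimens
#>   Chao1 richness: 67 (+/- 9 SE); terminal slope 0.078

summary(fit)
#> Richness by order:
#>           group motus   n      chao slope              category n_families
#>           Total    53 253 67 (+/-9) 0.078 modestly_undersampled         31
#>    Mesostigmata     7  34 13 (+/-7) 0.110     very_undersampled          5
#>  Sarcoptiformes    19  51 26 (+/-6) 0.194     very_undersampled         12
#>  Trombidiformes    27 168 28 (+/-2) 0.030 modestly_undersampled         14
#>
#> ANOSIM (forested vs non-forested):
#>   Mesostigmata: R = 0.692, p = 0.022
#>   Sarcoptiformes: R = 0.800, p = 0.01
#>   Trombidiformes: R = 0.878, p = 0.01
```

Reading this: 256 of 349 attempted specimens yielded a barcode (73.4%);
253 pass the analysis grade and collapse into 53 MOTUs at 15 changes.
The Chao1 estimate of 67 (the true pool holds 60 species, of which only
some were drawn) and the terminal slope of 0.078 MOTUs/specimen both say
sampling is incomplete. ANOSIM confirms the strong forested vs
non-forested turnover the generator planted (R near 1, p ≈ 0.01 at 999
permutations). Passing `outdir =` writes the delimited reports, Newick
dendrograms, and a checksum manifest; `compare_surveys()` quantifies the
richness added by supplementary qualitative sampling.

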