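# glioquant

Quantification of DCX-, OLIG2- and NES-positive cells in multiplex
immunofluorescence (IF) images of glioblastoma tissue, and CNV-based
cancer/normal annotation of single cells — with ground-truthed synthetic
generators so every stage is testable without clinical or controlled-access
data.

Glioblastoma studies of marker expression face two recurring computational
tasks. First, counting which cells in a four-channel IF image
(Hoechst/nuclei, OLIG2, NES, DCX) are positive for each marker, where OLIG2
is a nuclear signal and DCX/NES are perinuclear cytoskeletal signals.
Second, deciding which cells in a single-cell RNA-seq matrix are malignant,
using the canonical GBM aberrations — chromosome 7 gain or chromosome 10
loss — read off smoothed expression residuals against a non-cancer
reference. `glioquant` implements both arms plus the nonparametric
statistics used to compare marker frequencies across tissue sites and
sequential resections.

## The method in brief

**Imaging arm** — per random square counting spot:

1. nuclei = Otsu-thresholded Hoechst components filtered to "oval and
   coherent" figures (area ∈ [80, 8000] px², solidity ≥ 0.8,
   eccentricity ≤ 0.95);
2. a nuclei-seeded **Voronoi tessellation** assigns every pixel to its
   nearest nucleus centroid (ties to the lowest label);
3. positivity: OLIG2⁺ iff marker foreground covers ≥ 10% of the nucleus
   mask (**overlap rule**); DCX⁺/NES⁺ iff a marker component intersects the
   3-px dilation of the nucleus mask, a component adjacent to several
   nuclei counting *all* of them (**adjacency rule**);
4. output: total cells plus counts/frequencies of all 7 marker combinations.

**Expression arm** — QC (UMIs > 1000, 500 < genes < 5000, mito < 10%,
strict), log-normalisation `ln(1 + 10⁴·c/T)`, reference-centred moving-
average CNV scores per chromosome (window 101 genes, truncated at
chromosome ends), and the rule

```
status = cancer  iff  chr7 score >= +0.15  OR  chr10 score <= -0.15
```

**Statistics** — per-image averaging of spot subsamples, two-sided Wilcoxon
rank-sum (unpaired sites) and signed-rank (margin vs adjacent tumour,
paired within case × resection), Kruskal–Wallis over resections, Spearman
correlation structure.

## Worked example

```r
library(glioquant)

# a ground-truthed synthetic field: 250 cells, true positive fractions
# OLIG2 0.10, NES 0.20, DCX 0.05
sim <- generate_if_image(image_sim_spec(seed = 1))
q   <- quantify_spot(sim$image)
q$record[, c("total_cells", "freq_olig2", "freq_nes", "freq_dcx")]
#>   total_cells freq_olig2 freq_nes freq_dcx
#> 1         250       0.12    0.212     0.04

# the generator's truth for this field, for comparison
colMeans(sim$truth[, c("olig2", "nes", "dcx")])
#> olig2   nes   dcx
#> 0.120 0.212 0.040
```

The quantifier recovers this field's true per-spot fractions exactly: all
250 nuclei are detected and every positivity call matches the generated
truth (the 0.120/0.212/0.040 are this seed's Binomial draws around the
nominal 0.10/0.20/0.05).

```r
# expression arm: planted 40% cancer (chr7 x1.5, chr10 x0.5) + reference
sce  <- generate_expression_matrix(expr_sim_spec(seed = 11))
sce  <- log_normalize(qc_filter(sce))
ref  <- colnames(sce)[sce$truth_label == "reference"]
calls <- classify_malignancy(cnv_score(sce, reference = ref))
table(called = calls$status[sce$truth_label != "reference"],
      truth  = sce$truth_label[sce$truth_label != "reference"])
#>         truth
#> called   cancer normal
#>   cancer    740     31
#>   normal      0   1069
```

i.e. sensitivity 1.00 and specificity 0.97 on this seed's 1840 tumour
cells that pass QC.

The numbered scripts under `analysis/` run the full workflow end to end
(simulate fields → quantify spots → site statistics → expression/CNV →
deterministic pipeline demo) and write their tables under `results/`.

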