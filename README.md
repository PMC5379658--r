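# TNBCconcord

Molecular subtyping of triple-negative breast cancer (TNBC) is performed by
correlating a tumor's expression profile against per-subtype reference
centroids (BL1, BL2, M, LAR, ...) and calling the best-correlated subtype.
For clinical use the same call must be reproducible when the input changes
from fresh-frozen (FF), poly-A-selected RNA to the degraded,
ribosomal-depleted RNA of formalin-fixed paraffin-embedded (FFPE) blocks —
and the two preparations enrich for systematically different transcripts.

**TNBCconcord** is an R package for researchers who need to quantify that
cross-preparation robustness. It provides:

- **Nearest-centroid subtyping** on FPKM-normalized counts with a
  *prediction strength* (the called subtype's correlation ρ) and a
  *prediction confidence* (ρ₁ − ρ₂, the gap to the runner-up subtype),
  plus an `UNCLASSIFIED` outcome for weakly correlated samples.
- **Paired concordance statistics**: the concordance rate over evaluable
  pairs with a two-sided Clopper–Pearson exact binomial interval
  (lower = Beta⁻¹(α/2; k, n−k+1), upper = Beta⁻¹(1−α/2; k+1, n−k)),
  accuracy-vs-confidence curves, and the smallest confidence cutoff
  reaching a target accuracy.
- **Differential-transcript identification** between preparations: a
  self-contained negative-binomial Wald test with median-of-ratios
  normalization, method-of-moments dispersion, Benjamini–Hochberg FDR, and
  the field-standard thresholds (|FC| ≥ 2, q ≤ 0.05, mean count > 4).
- **Bias characterization**: transcript-class accounting of differential
  transcripts, transcript-length bias (Mann–Whitney on log₁₀ length),
  exon-level 3′ positional bias (Spearman ρ of exon counts vs exon index),
  hypergeometric gene-set overrepresentation, rRNA fractions and
  read-category summaries.
- **Centroid gene-set reduction** (`reduceCentroids`) to re-call subtypes
  after excluding preparation-sensitive genes.
- A **synthetic paired FF/FFPE cohort generator** with full ground truth —
  subtype signatures with tumor purity mixing, FFPE class-selective
  enrichment, FF poly-A length and 3′ bias, MiSeq/HiSeq depth regimes and
  age-dependent degradation — so every stage of the pipeline is testable
  without any external data.

## Worked example

```r
library(TNBCconcord)

sim <- simulateCohort(simConfig(seed = 1))          # 21 FF/FFPE pairs, 5000 genes
resFF   <- subtypeCohort(fpkmNormalize(sim$countsFF,   sim$annotation), sim$centroids)
resFFPE <- subtypeCohort(fpkmNormalize(sim$countsFFPE, sim$annotation), sim$centroids)
head(resFF[, c("sample_id", "call", "strength", "confidence")], 3)
#>   sample_id call  strength confidence
#> 1    FF_P01  LAR 0.9511550 0.11443626
#> 2    FF_P02  LAR 0.9388142 0.09838989
#> 3    FF_P03    M 0.9602253 0.20535568

concordance(resFF, resFFPE, sim$design)
#> ConcordanceReport: 20/21 concordant = 95.2% [CI 76.2%, 99.9%] (level 0.95)
```

20 of the 21 tumor pairs received the identical subtype call from both
preparations; the bracket is the exact binomial 95% interval on that rate.
Differential transcripts between the preparations, and what kind they are:

```r
counts <- ExpressionMatrix(cbind(exprValues(sim$countsFF),
                                 exprValues(sim$countsFFPE)), "count")
de <- nbWaldTest(counts, rep(c("FF", "FFPE"), each = 21))
sum(de$is_differential)
#> [1] 699

tab <- classTable(de, sim$annotation)
tab[tab$transcript_class %in% c("snoRNA", "protein_coding", "Total"),
    c(1, 2, 3, 4, 5, 7)]
#>  transcript_class n_all n_differential pct_differential n_ffpe n_ff
#>            snoRNA    52             39          75.0000     39    0
#>    protein_coding  3061            362          11.8262     33  329
#>             Total  5000            699          13.9800    370  329
```

Small nucleolar RNAs are overwhelmingly FFPE-enriched (ribosomal depletion
retains them; poly-A selection does not), while protein-coding transcripts
are the least differential class — the same qualitative fingerprint seen in
real FF/FFPE comparisons. `runPipeline()` chains all stages (subtyping,
concordance, differential transcripts, removal/recorrelation, bias
summaries) from one config and writes a JSON report plus per-stage TSVs.

## Documentation

The methods vignette (`vignettes/ffpe-concordance-methods.Rmd`) describes
the statistical model of every stage, the synthetic cohort's design and its
limitations, and the numerical choices (tie-breaking, pseudocounts,
thresholds) in detail.
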