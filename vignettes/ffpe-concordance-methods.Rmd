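---
title: "Methods: TNBC subtype concordance between FF and FFPE RNA-seq"
author: "TNBCconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TNBC subtype concordance between FF and FFPE RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TNBCconcord)
```

# The problem

Triple-negative breast cancer is molecularly heterogeneous; its subtypes
(basal-like 1/2, mesenchymal, luminal-AR, ...) are defined by reference
expression centroids, and a tumor is subtyped by its strongest correlation
to a centroid. Clinical material is almost always formalin-fixed and
paraffin-embedded (FFPE): RNA from such blocks is degraded, cannot be
poly-A-selected, and is instead ribosomal-depleted — so its transcriptome
composition differs systematically from the fresh-frozen (FF),
poly-A-selected RNA that classifiers are usually trained on. This package
implements the full analytical chain needed to ask: *do subtype calls
survive the change of preparation, and which transcripts are responsible
when they do not?*

# Subtyping model

For sample $x$ and centroid matrix $C$ (genes $\times$ subtypes), the call
is

$$\hat{s}(x) = \arg\max_s \; \rho\big(x_{G}, C_{G,s}\big),$$

where $G$ is the intersection of the sample's genes with the centroid
genes and $\rho$ is Spearman's rank correlation on $\log_2(\mathrm{FPKM}+1)$.

* **Correlation type.** Spearman is the default: rank-based correlation is
  invariant to any monotone transform of the sample vector, which buys
  robustness across platforms and normalizations. Pearson is available via
  `subtypeOptions(correlationMethod = "pearson")`, for which the
  $\log_2(x+1)$ transform matters (pseudocount 1 keeps zero-count genes
  finite).
* **Prediction strength** is the called subtype's $\rho$; **prediction
  confidence** is $\rho_{(1)}-\rho_{(2)}$, the gap to the runner-up, in
  $[0, 2]$.
* **UNCLASSIFIED.** A sample with $\rho_{(1)} <$ `minStrength` (default
  0.1) is not called; a zero-variance expression vector is UNCLASSIFIED
  with all correlations set to 0 and a warning. The 0.1 default is a
  transparent operating point, not an inference rule; a permutation-based
  criterion is deliberately out of scope.
* **Ties** in the top correlation break lexicographically by subtype name.
  Such calls have confidence 0, i.e. they flag themselves as worthless;
  the rule only exists so results are deterministic.
* **Gene overlap.** At least `minGeneOverlapFraction` (default 0.5) of the
  centroid genes must be present, since platforms measure overlapping but
  unequal gene sets; below that the sample errors out rather than being
  silently called on too few genes.

FPKM normalization is the classical
$10^9 \cdot k_{gs} / (\ell_g \cdot N_s)$ with transcript length $\ell_g$
and library size $N_s$; it removes length and depth so that profiles are
comparable to length-agnostic centroids.

# Concordance statistics

A pair of results (FF and FFPE members of one tumor) is *concordant* iff
the calls are identical. Pairs with an UNCLASSIFIED member are excluded
from the evaluable set by default (they are listed with reasons;
`excludeUnclassified = FALSE` instead counts them as discordant unless both
members are UNCLASSIFIED). The concordance rate $k/n$ gets a two-sided
Clopper–Pearson exact interval,

$$\big[\,B^{-1}(\alpha/2;\,k,\,n-k+1),\; B^{-1}(1-\alpha/2;\,k+1,\,n-k)\,\big],$$

with the conventional boundary values 0 at $k=0$ and 1 at $k=n$. The exact
interval is conservative (coverage $\ge$ nominal), which the test suite
verifies by simulation.

The accuracy-vs-confidence curve restricts to pairs whose *minimum* member
confidence exceeds a cutoff — the minimum is the conservative combination
rule for a pair — and reports the concordant fraction on a cutoff grid
(default 0 to 1 by 0.01, cumulative "$\ge$ cutoff" strata rather than
bins, so the curve has a single crossing of any target). The smallest
cutoff reaching a target accuracy additionally requires at least 5 backing
pairs, so near-empty strata cannot declare an operating point.

Group comparisons of per-pair Spearman correlations (HiSeq vs MiSeq, new
vs old blocks) use the two-sided Mann–Whitney U test: exact when
$\min(n_1,n_2) \le 8$ without ties, otherwise the normal approximation
with tie correction.

# Differential transcripts between preparations

The test is a self-contained negative-binomial Wald procedure:

1. **Normalization** by median-of-ratios size factors (genes with any zero
   count excluded from the reference; total-count fallback with a warning
   when no gene is all-nonzero; factors rescaled to geometric mean 1).
2. **Dispersion** per gene by method of moments,
   $\alpha_g = \max(\text{floor},\, (\widehat{var}-\hat\mu)/\hat\mu^2)$,
   estimated within each condition and pooled with degree-of-freedom
   weights. The floor is $10^{-8}$.
3. **Effect**: $\log_2\mathrm{FC} = \log_2\frac{\bar\mu_{FFPE}+0.5}{\bar\mu_{FF}+0.5}$
   (pseudocount 0.5 keeps empty genes finite), with a delta-method
   standard error under $\mathrm{NB}(\mu, \alpha)$ and a two-sided normal
   p-value; Benjamini–Hochberg q-values.
4. **Thresholds**: differential iff $q \le 0.05$, $|\mathrm{FC}| \ge 2$
   and mean normalized count $> 4$ (all configurable via `deOptions()`),
   with the enrichment direction given by the sign of the fold change.
   The q threshold is 0.05: the adjusted-p criterion is the operative
   definition throughout.

**Pairing is not modeled by the test.** The FF and FFPE libraries of one
tumor share the tumor's expression deviations, so the unpaired Wald test
over-estimates the within-group variance and is *conservative* on such
data (measured type-I error $\sim 10^{-3}$ when tumor-level variation is
present). Calibration is therefore assessed on an exchangeable null —
independent NB samples with gene-wise dispersions deliberately mismatched
up to $\pm 2\times$ from the fitted model — where the type-I error at
$p \le 0.05$ sits within $0.05 \pm 0.02$ among genes above the count
filter. Genes with essentially zero counts have degenerate Wald statistics
(p forced to 1, flagged), so calibration statements apply to testable
genes.

The *removal experiment* recomputes per-pair Spearman correlations on the
complement of a differential set and tests the per-pair deltas with a
Wilcoxon signed-rank test (not computable with a single pair; the
complement must keep at least 10 genes). Removing the *ground-truth*
differential genes of the synthetic cohort reliably increases the mean
pair correlation; removing the *detected* set helps less at moderate
detection power, because detection favors well-measured genes and misses
truly preparation-sensitive low-abundance ones — a caveat worth
remembering when interpreting the same experiment on real data.

# Transcript-bias characterization

* **Class table**: per transcript class (15-class vocabulary: rRNA, misc
  RNA, snoRNA, snRNA, sense intronic, 3′ overlapping ncRNA, miRNA,
  mitochondrial RNA, pseudogene, antisense, sense overlapping, lincRNA,
  processed transcript, polymorphic pseudogene, protein coding), the
  count of transcripts, the differential count (% of class) and the
  FFPE/FF-enriched split (% of the class's differential count), plus a
  totals row; the row/column identities are asserted on every call.
* **Length bias**: group summaries of transcript length and a two-sided
  Mann–Whitney test on $\log_{10}$ length between FF- and FFPE-enriched
  transcripts (skipped with a notice for groups under 3 genes).
* **3′ positional bias**: per gene with $\ge 4$ exons, the Spearman
  correlation between exon index (5′→3′) and the group-mean
  total-normalized exon count. Positive values mean coverage piling
  toward the 3′ end — the signature of poly-A selection on partially
  degraded transcripts. Rank correlation against the exon index was
  chosen over curve fitting: it is assumption-free, scale-invariant (each
  sample is normalized to its total first) and directly testable.
* **Gene-set overrepresentation** is the upper-tail hypergeometric test
  ($p = P(X \ge k)$ with universe $N$, set $K$, query $n$), BH-adjusted
  within a collection — i.e. the "overlap" formulation matching
  count-based enrichment tables, not ranked-list GSEA. Gene sets load
  from GMT files; no curated collections ship with the package.
* **Read categories**: on-target/intronic/intergenic percentages use
  *mapped* reads as denominator; the unmapped percentage uses total
  reads. The two denominators are deliberate and stated because summaries
  of this kind habitually mix them.
* **rRNA fraction**: counts in rRNA-class genes over total counts, per
  sample — the ribosomal-depletion efficiency measure.

# The synthetic cohort

`simConfig()` / `simulateCohort()` generate paired FF/FFPE counts with
known truth. The default configuration *is* the emulated study design:
21 tumor pairs (4 of them >10-year-old blocks), MiSeq-like ($1.3\times
10^7$) and HiSeq-like ($8\times 10^7$) total aligned reads, FF libraries
~84% on-target versus ~31% for FFPE, and a transcript-class census
matching a 27,577-transcript transcriptome. Per-gene counts are scaled by
$n_{genes}/27577$ so a 5,000-gene panel (the default size, chosen so the
full pipeline runs in seconds) sees the same per-gene depth as the full
transcriptome at those read totals.

The generative model, per gene $g$ and tumor $j$:

* baseline abundance $b_g \sim \mathrm{LogNormal}(0, 3)$ — the wide
  dynamic range is what leaves low-abundance genes in the shot-noise
  regime at MiSeq depth;
* subtype structure: each subtype has a signature
  $\delta_{gs} \sim N(0, 2.5^2)$ in $\log_2$ over 500 centroid genes;
  tumor $j$ of subtype $s$ expresses
  $w_j\,\delta_{gs} + (1-w_j)\,\delta_{gs'}$ with purity
  $w_j \sim U(0.5, 1)$ and a random second subtype $s'$. Tumors near
  $w = 0.5$ genuinely correlate with two centroids: they are the source
  of low-confidence and discordant calls, mirroring how mixed subtype
  signals behave in practice. Subtype prevalences default to the
  TCGA-like distribution (BL1 0.323, BL2 0.188, M 0.302, LAR 0.188);
* per-tumor deviations $\sim N(0, 0.7^2)$ $\log_2$, *shared by the FF and
  FFPE members* of the pair (it is the same tumor);
* preparation biases: FFPE multiplies each class by its
  ribosomal-depletion retention factor (defaults skew small non-poly-A
  RNAs up to $8\times$); FF retention decays exponentially in transcript
  length at rate $\ln 2 / 6000$ per bp (2-fold loss at 6 kb); FFPE
  samples get age-dependent degradation noise ($\log_2$ sd 0.15 for new,
  0.6 for old blocks), FF samples a small 0.1;
* counts are negative binomial with gene-wise dispersions spread
  uniformly on the log scale within $2\times$ of 0.05; exon-level counts
  for 30 long multi-exon genes are multinomial with FF weights decaying
  exponentially away from the 3′ end (rate 2), FFPE weights proportional
  to exon length only.

**Ground-truth fold changes are median-centered.** Counts are relative
abundances, so only fold changes relative to the compositional anchor of
the normalization (the median gene, for median-of-ratios) are
identifiable; the generator's `true_log2_fc` is therefore the raw
FFPE/FF log-ratio minus its median across genes, and a gene is
truth-differential when that identifiable effect reaches 2-fold.

The centroid file contains the noiseless expected FPKM of a pure tumor of
each subtype — the classifier's reference is clean even though every
emitted sample is biased and noisy, as in reality where centroids derive
from large training cohorts.

Everything is reproducible: the config carries a mandatory seed and
identical configs give bit-identical outputs;
`simulatePairedPlatform()` emits the *same* underlying cohort at both
depth regimes with independent count sampling.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artifacts (mapping multi-reads, GC
bias, fragmentation chemistry), batch effects between sequencing runs,
stromal/immune admixture with its own expression program (tumor noise is
unstructured), annotation errors, and the exact correlation structure of
a real centroid training cohort. Results on synthetic cohorts demonstrate
that the *pipeline* recovers planted structure of realistic magnitude,
not that any particular real cohort will behave identically.

# Numerical and design choices

* Problem sizes in the test suite: unit tests run 1,500-gene/8-pair
  cohorts; the acceptance-level properties use the full default
  (5,000 genes, 21 pairs) and 20 replicate cohorts for the depth
  comparison — sizes chosen so the whole suite completes in well under a
  minute per file while keeping Monte-Carlo error small relative to the
  margins tested.
* Matrices are dense; at $\le$ 30k genes and tens of samples sparsity
  buys nothing.
* Gene identifiers match as exact strings after whitespace trimming; no
  alias resolution (that belongs to the user's annotation pipeline).
  HTSeq bookkeeping rows (`__no_feature`, ...) are stripped at load and
  reported.
* GTF-derived annotation takes `gene_biotype` through an overridable
  mapping (`defaultBiotypeMap()`: pseudogene flavours collapse to
  pseudogene, Mt rRNA/tRNA to mitochondrial RNA, IG/TR genes to protein
  coding) and computes union-of-exon lengths from the 1-based inclusive
  GTF coordinates.
* TSV round trips are bit-exact (`%.17g` serialization).
* `runPipeline()` orchestrates the stages from one R or YAML config; any
  stage failure is recorded by name and dependent stages are skipped. The
  report is a pure function of (inputs, options, seed) and carries the
  options and seed for reproducibility.

# Known limitations

* The NB Wald test ignores pairing (conservative on paired designs) and
  uses moment dispersions without shrinkage; it is a calibrated,
  transparent reference implementation, not a drop-in replacement for
  shrinkage-based DE frameworks.
* The UNCLASSIFIED rule is a fixed strength threshold; with the synthetic
  cohort's high absolute correlations it rarely triggers, so UNCLASSIFIED
  handling is exercised mainly through constructed cases.
* Confidence combines across a pair by the minimum; other choices
  (mean, product) would shift the accuracy-confidence curve and were not
  explored.
* The subtyping pipeline is centroid-count-agnostic (any $\ge 2$ subtypes
  work), but all defaults are tuned to the four-subtype setting.
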