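---
title: "Methods: prioritizing acetyltransferase genes coupled to EMT activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing acetyltransferase genes coupled to EMT activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylprio)
```

## Scope and model

`acetylprio` screens a histone acetyltransferase (HAT) gene collection
against two axes measured in the same staged expression cohort: two-group
differential expression (cancer vs normal) and coupling to a per-sample
epithelial–mesenchymal transition (EMT) activity score. The cohort is a
log2-scale genes × samples matrix with stage labels `normal`, `CIN1`–`CIN3`,
`cancer`. Candidates are the genes that are simultaneously among the top
30 % of the collection by the composite rank score and positively correlated
with the EMT score; each candidate is then validated by gene set enrichment
of its genome-wide correlation profile against the EMT set.

The procedure assumes: expression is already normalized and log2-scaled
(processed microarray convention; `log2_transform = TRUE` applies
`log2(x + 1)` for raw input); samples are exchangeable within groups (no
batch or covariate structure); and the EMT gene set meaningfully tracks the
pathway in this tissue.

### Per-sample EMT score (ssGSEA)

For each sample, genes are ordered by decreasing expression, with ties broken
lexicographically by gene id so results are identical across platforms. The
gene at position $i$ from the bottom carries integer rank weight $r_i$
($r = N$ for the highest-expressed gene). For a set $S$ the score walks the
ranking and sums the deviation between the weighted cumulative hit fraction
and the uniform cumulative miss fraction:

$$\mathrm{ES} = \sum_{i=1}^{N}\Big[\frac{\sum_{j \le i,\, g_j \in S} r_j^{\alpha}}
{\sum_{g \in S} r_g^{\alpha}} - \frac{\#\{j \le i : g_j \notin S\}}{N - |S|}\Big].$$

The score depends only on within-sample ranks, so any strictly increasing
per-sample transform leaves it unchanged — the property that makes it usable
across heterogeneously scaled samples.

* `alpha` (default **0.25**, dimensionless): rank-weight exponent. 0.25 is
  the dominant convention in widely used single-sample implementations; 0
  gives the unweighted KS-style walk. Reproducibility requires pinning one
  variant, so the default is explicit and configurable rather than implied.
* `normalize` (default **TRUE**): divide all sample scores by their
  cross-sample range (max − min). This affects only the scale, never the
  ordering of samples, and is a no-op for a constant score vector. Whether to
  normalize is genuinely open in common practice; both behaviours are
  supported.

One caveat is documented rather than assumed away: for $\alpha > 0$ the score
is *not* monotone under single-rank promotions of a set member. Promoting a
member increases the hit-weight denominator and can dilute the plateau
contributed by a high-ranking member; the minimal counterexample ($N = 6$,
weights $6..1$, $S$ = ranks 1 and 6, swap ranks 5/6, $\alpha = 1$, ES drops
by $5/140$) is frozen in the test suite. For $\alpha = 0$ monotonicity holds
and is tested as a property.

### Composite rank score

For every HAT gene, a two-sided Wilcoxon rank-sum test compares cancer
against normal samples, and the fold change is computed on the log2 scale:
$\log_2 FC$ = (mean log2 expression in cancer) − (mean log2 expression in
normal), $FC = 2^{\log_2 FC}$. The composite score is

$$R = -\log_{10}(p)\,\times\,\log_2(FC).$$

Computing FC as a difference of log-scale means (rather than a ratio of
linear means) matches microarray convention and makes $\mathrm{sign}(R)$
equal the regulation direction. The Wilcoxon p-value is exact (enumeration)
when the smaller group has ≤ 8 samples and the data are untied, otherwise the
normal approximation with tie and continuity correction; p is clamped to
$[10^{-300}, 1]$ so $R$ is always finite, and fully tied data return $p = 1$.
No multiple-testing correction enters the decision rule — the screen's
contract is the raw $p \le 0.05$ — but a Benjamini–Hochberg column is emitted
for information.

`select_top()` keeps the first $\lfloor 0.30\,n \rfloor$ genes (minimum one)
by descending signed $R$, ties broken by gene id. Ranking by *signed* R means
strongly down-regulated genes sort last; the subsequent overlap additionally
requires `de_class == "up"`, so the candidate set is insensitive to whether
the up-filter is applied before or after the 30 % cut whenever enough
up-regulated genes exist. Both orders are available
(`require_up`, `top_fraction`).

### EMT correlation screen

Spearman correlation (Pearson on midranks, tie-aware) between each HAT
gene and the EMT score over **all** samples — the premalignant grades carry
most of the activity gradient, and restricting to cancer-only samples is
left as a caller-side subset. The two-sided p-value uses the t approximation
with $n - 2$ degrees of freedom, accurate at the design's $n = 128$; an exact
permutation option exists for $n < 10$. A gene passes when $p \le 0.05$
**and** $|SCC| \ge 0.3$, both inclusive — boundary values pass, and the test
suite pins that semantics. At $n = 128$ the $|SCC| \ge 0.3$ arm is the
binding constraint ($|SCC| = 0.3$ has $p \approx 6 \times 10^{-4}$), which is
why the joint null pass rate sits far below 5 %.

### Candidate GSEA validation

For a candidate $g$, all other genes are ranked by their Spearman correlation
with $g$, and the EMT set is tested with the weighted Kolmogorov–Smirnov
statistic: hits advance the running sum by $|w|^{e}$ (normalized over hits),
misses retreat by $1/(N - |S|)$; ES is the signed maximum-magnitude deviation,
bounded in $[-1, 1]$. The default exponent $e = 1$ weights by correlation
magnitude; $e = 0$ gives the classic KS form. Because the input is a single
correlation profile rather than a phenotype-labelled matrix, the null
permutes *gene labels* (random same-size sets), a deliberate departure from
phenotype-permutation GSEA: $p = (1 + \#\{|ES_0| \ge |ES|\})/(n_{perm} + 1)$,
never zero by construction. The leading edge is the set members at or before
the peak (at or after it for negative ES). When the extreme positive and
negative deviations tie in magnitude *exactly* — reachable because miss steps
are integer multiples of $1/(N-|S|)$ — only $|ES|$ is well defined and the
reported sign is floating-point-order dependent; the oracle tests compare
magnitudes at such ties.

## The synthetic cohort

`synthetic_spec()` fixes the study conditions the pipeline is demonstrated
under; `generate_cohort()` draws from the generative model

* activity $a_j \sim N(\mu_{stage(j)}, \sigma_a^2)$, with
  $\mu = (0, 0.5, 1, 1.5, 2)$ across normal → cancer and $\sigma_a = 0.5$;
* EMT programme gene: $x_{ij} = b_i + \lambda_i a_j + \varepsilon_{ij}$,
  $\lambda_i \sim U(0.5, 1.5)$ (200 genes);
* planted candidate: $x_{ij} = b_i + \delta\,\mathbf{1}[stage = cancer] +
  \gamma a_j + \varepsilon_{ij}$, $\delta = 1$ log2 unit, $\gamma = 0.6$
  (7 of 88 collection genes, chosen by the seeded RNG);
* acetyl-null and background genes: baseline plus noise;
* $b_i \sim N(7, 2^2)$ log2 units, $\varepsilon_{ij} \sim N(0, 1)$,
  5000 background genes.

Stage sizes default to 24/14/22/40/28 (total 128) — the per-stage composition
of the public cervical cohort this design emulates; only the total is
essential to the statistics. Under this model the expected cancer-vs-normal
log2 difference of a planted gene is $\delta + \gamma(\mu_{cancer} -
\mu_{normal}) = 2.2$, and the recovery checks measure `log2fc` bias against
that model-implied value, not against $\delta$ alone. `null_cohort()` zeroes
$\delta$, $\gamma$ and all $\lambda_i$ for calibration runs.

What the generator does *not* emulate: probe-level artefacts, batch and
array effects, heavy-tailed or heteroscedastic noise (a t-noise stress option
was considered and rejected as out of scope), correlated background genes,
and misspecified gene sets — the EMT set used for scoring is the set used
for generation. Passing tests therefore demonstrate internal correctness and
calibration of the statistics, not robustness to annotation error or
real-array noise structure.

## Numerical and design choices

* Duplicate gene ids collapse to the highest-mean row; rows with missing
  values are dropped; both are counted in messages (microarray convention).
* The two-group `state` label maps stage `normal` → normal, `cancer` →
  cancer, and CIN grades → `NA`: CIN samples are excluded from the Wilcoxon /
  fold-change comparison but fully used for scoring and correlation.
* All ordering operations (rank ties, R-score ties, profile ties) break ties
  lexicographically by gene id, making every output deterministic.
* Degenerate inputs raise classed errors (`acetylprio_empty_set`,
  `acetylprio_degenerate_complement`, `acetylprio_degenerate_input`,
  `acetylprio_insufficient_samples`, `acetylprio_alignment_error`,
  `acetylprio_domain_error`) rather than propagating NaN.
* Reports (`write_pipeline_outputs()`) contain parameters, seeds and counts
  but no timestamps, so an identical configuration reproduces byte-identical
  output; GSEA nulls restore the caller's RNG state.
* Oracle-equivalence tests run the running-sum statistics against naive
  double-loop reimplementations at $10^{-12}$ absolute tolerance (1000
  random instances each, $N \le 50$–$60$); Wilcoxon p-values are checked
  against exhaustive label enumeration for group sizes ≤ 8. Calibration runs
  use a full-size null cohort (≈5300 genes × 128 samples) for DE and screen
  rates and a 1200-gene profile with 500 random sets × 1000 permutations for
  permutation-p uniformity; recovery runs use 25 independent default cohorts
  with 200 permutations per candidate GSEA. These sizes are the package's
  chosen demonstration scale — large enough for stable rates, small enough to
  run routinely.
* IHC staining components follow the usual immunoreactive-score scales
  (intensity 0–3, proportion 0–4); under these scales no product equals 5,
  so the ≥ 6 high / ≤ 4 low cutoffs classify every reachable index. The
  scales are a convention of this package, the cutoffs are the study's.

## Limitations

Beyond the generator simplifications above: the screen tests marginal
correlation only (no partial or stage-stratified correlation); a single gene
set is scored per run (no multi-set projection or NES/FDR machinery); the
Spearman p is approximate for very small cohorts (use `exact = TRUE`); and
the weighted ssGSEA non-monotonicity means small rank perturbations can
nudge scores in either direction when $\alpha > 0$.
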