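---
title: "Methods: motif-based ridge attribution of differential accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based ridge attribution of differential accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistical methods it
implements, the parameters that matter, the design decisions taken where
the design was genuinely open, and the limits of what the synthetic-data
tests demonstrate.

# The model

The core object is a linear model of differential chromatin
accessibility. For a consensus atlas of $n$ ATAC-seq peaks and $p$
transcription-factor motif groups, let $X \in \{0,1\}^{n \times p}$ be
the binary peak-by-motif matrix ($x_{ij} = 1$ iff at least one instance
of a motif in group $j$ occurs in peak $i$, either strand) and
$y \in \mathbb{R}^n$ the per-peak log2 fold change of accessibility
between two cell populations. We fit the ridge estimator on
column-centered $X$ with an unpenalized intercept:

$$\hat\beta(\lambda) = (X_c^\top X_c + \lambda I)^{-1} X_c^\top y_c .$$

A positive $\hat\beta_j$ means motif $j$'s presence predicts gain of
accessibility in the comparison, which is read as increased activity of
the corresponding TFs. Two comparisons are fit separately (called `svn`
and `svr` for stable-vs-negative and stable-vs-recent populations), and
their paired coefficients are categorized by significance in neither,
one, or both models.

**Assumptions.** Effects are additive in motif presence; occurrence
counts beyond the first, positional information and motif-motif
interactions are discarded deliberately (binary predictors keep the
presence/absence semantics interpretable). Peaks are treated as
exchangeable observations; spatial correlation along the genome is
ignored.

## Choosing the penalty

With `lambda = "auto"` (the default), candidates are built from the
principal-components regression view. Writing the SVD
$X_c = U D V^\top$ with PC coefficients
$\hat\alpha_j = u_j^\top y_c / d_j$, each rank $r$ yields a candidate

$$\lambda_r = \frac{r\,\hat\sigma^2}{\sum_{j \le r} \hat\alpha_j^2},$$

a PCA-based generalization of the classical Hoerl–Kennard–Baldwin
estimator, with $\hat\sigma^2$ the OLS residual variance. The exact
rule used by the semi-automatic estimator in the original ridge
literature is not fully specified by citation alone, so the package
sweeps $r = 1..\mathrm{rank}(X_c)$ and keeps the candidate minimizing
exact leave-one-out prediction error (PRESS), computable in closed form
from the SVD. This is a documented surrogate, not a bit-exact
reimplementation of any particular package version.

## Coefficient significance

P-values use the asymptotic sampling variance of the ridge estimator
(Cule-style test): with $W = (X_c^\top X_c + \lambda I)^{-1}$,
$\operatorname{Var}(\hat\beta) = \hat\sigma^2\, W X_c^\top X_c W$, and
$z_j = \hat\beta_j / \mathrm{se}_j$ is referred to a standard normal,
two-sided. No multiple-testing correction is applied to these
coefficient p-values, matching the raw $P < 0.001$ convention used for
calling significant motifs; the threshold is strict (`<`).

## Zeroed-out models and Δcor attribution

For each motif $m$, the model is refit with column $m$ removed (a
"zeroed-out" model). For a peak subset $S$ (typically the peaks linked
to a bulk gene cluster),

$$\Delta\mathrm{cor}(m) = \operatorname{cor}(y_S, \hat y_S^{\text{full}})
  - \operatorname{cor}(y_S, \hat y_S^{(-m)}),$$

so a large positive value flags a motif that disproportionately carries
predictive accuracy at those peaks. By default $\lambda$ is re-selected
for every zeroed-out model under the same policy as the full fit (the
models are described as fitted "as above"); a `lambda_policy = "freeze"`
flag reuses the full model's $\lambda$ instead.

Two degenerate regimes are worth knowing. If motif $m$ is *absent* from
every subset peak and its column is orthogonal to the rest, the full and
zeroed predictions coincide on $S$ and $\Delta\mathrm{cor}(m) = 0$.
Symmetrically, if $m$ is *present in every* subset peak, its column is
constant on $S$, the two predictions differ by a constant, and Pearson
correlation is shift-invariant — again $\Delta\mathrm{cor}(m) \approx 0$
even when $\beta_m$ is large. Δcor therefore attributes motifs only at
subsets where their presence *varies*; the package's tests evaluate
attribution on mixed subsets (peaks with and without the motif), which
is also the regime of real gene-cluster subsets, and assert the
saturated-subset degeneracy explicitly.

# Peak atlas construction

Per-population narrowPeak calls are concatenated and clustered by
single-linkage interval overlap of at least 1 bp, with half-open
`[start, end)` coordinates throughout (bookended peaks do not cluster,
the `-d -1` convention). Each cluster merges by a two-case rule:

* **Full overlap** — all summits inside the cluster core
  $[\max(\text{starts}), \min(\text{ends}))$ (half-open containment):
  one output peak at the rounded mean start, summit and end.
* **Split** — otherwise, one output peak per distinct summit coordinate
  $s$, bounded by $\max\{\text{start} \le s\}$ and
  $\min\{\text{end} > s\}$ over *all* cluster members.

Numerical choices: mean coordinates round half away from zero (order-free
and deterministic; plain `round()` would round half to even), with the
end widened by 1 bp in the measure-zero case where rounding collapses the
interval. "Distinct summit" means exact coordinate equality — summits
1 bp apart produce separate peaks, as nothing in the merge rule licenses
collapsing near-equal summits. Split outputs may mutually overlap and are
retained as-is. Where the split boundaries could be read as coming only
from the peak owning the summit, we use any cluster member; both readings
agree on the test fixtures exercised here, and the choice is flagged in
the function documentation rather than silently assumed.

Filters retain peaks with width ≤ 3,500 bp and repeat fraction ≤ 70%
(strictly-greater eliminates, in both cases), computed from soft-masked
sequence (lowercase fraction) or a repeat BED (merged covered fraction);
sequence wins if both are given. Gene assignment uses precedence
promoter > intragenic > intergenic > unassigned with strand-aware
promoter windows (2,000 bp 5′, 500 bp 3′ of the TSS) and a 100 kb
intergenic window; distance ties break lexicographically by gene symbol
so runs are reproducible.

# Motif catalog

Instance calling uses the exact null distribution of the PWM log-odds
score: per-position scores (log2 of pseudocounted probability over
background) are integerized to at most `precision = 1000` bins per
position, and the distribution of the window score under an i.i.d.
background is computed by dynamic programming (convolution across
positions). The threshold is the smallest achievable score whose
upper-tail mass is ≤ the instance p-value (default `1e-4`); when even
the top score carries more mass (short or degenerate motifs), the
threshold is `Inf` and the motif matches nothing. Scanning uses the same
integerized scores, so scanner and threshold agree exactly; both strands
are scanned and windows overlapping non-ACGT bases are skipped. A
pseudocount of `1e-4` is added to PWM probabilities before log-odds; the
background defaults to uniform unless genome frequencies are supplied.

The staged filtering follows the order: expression filter (mean FPKM > 1
in any population, strict) → enrichment filter → best PWM per TF gene
(highest occurrence fraction, name tie-break) → similarity grouping →
group-level enrichment prune → scan to the binary matrix → 2% prevalence
floor (strictly-fewer eliminates). Enrichment compares occurrence
fractions against per-peak dinucleotide-shuffled backgrounds
(Altschul–Erickson shuffle, fixed seed) with a one-sided Fisher exact
test — implemented as the hypergeometric upper tail, which is the same
test — and Benjamini–Hochberg correction at adjusted `P < 0.01`.

Motif similarity is *not* a re-implementation of external
motif-comparison statistics. Either a precomputed E-value table is
supplied, or an internal surrogate is used: the best ungapped Pearson
correlation between probability matrices over all offsets and the
reverse-complement orientation, mapped to an E-value-like scale
$E = (1-r)\,n_{\text{pairs}}$. The surrogate is only meaningful near the
duplicate end of the scale, which is exactly where the grouping
threshold ($E < 10^{-5}$) operates. Grouping builds a graph (edge iff
below threshold *and* same protein family), takes connected components,
then repeatedly merges components sharing any TF gene until gene→group
is a function; the fixpoint is order-independent.

# Integration statistics

* **Gene filtering**: genes below the all-sample mean FPKM of a
  reference gene silent in the profiled lineage (default `Cd8a`), genes
  with zeros in a strict majority of samples, and Ig/TCR segment genes
  (configurable patterns, default `^Ig[hkl][vdj]`, `^Tr[abgd][vdj]`)
  are removed.
* **K-means** on per-gene Z-scores with k = 7, 50 restarts and a fixed
  seed; labels are relabeled by descending cluster size so cluster
  identity is deterministic. Constant genes (undefined Z) are set to 0.
  The k = n limit (every gene its own cluster, objective 0) is handled
  explicitly because the default Hartigan–Wong implementation rejects
  k = n.
* **Module scores** follow the standard binned-control scheme: score =
  mean log-normalized expression of set genes minus the mean of a
  pooled control set, 100 controls per set gene drawn with replacement
  from the gene's average-expression bin (24 bins), fixed seed. Genes
  absent from the matrix are dropped before control sampling, so they
  cannot perturb it.
* **Subset score matrices** drop subsets under 20 cells *before*
  Z-normalizing each gene-cluster's subset means (the ordering is not
  dictated anywhere; excluding first keeps tiny subsets from distorting
  the scale); zero-variance rows are reported as 0 with a warning.
* **Hypergeometric enrichment** is the upper tail $P(X \ge q)$,
  implemented as the survival function at $q-1$ — the tail convention
  that matches the stated enrichment intent.
* **Gene-set shift test**: two-sample two-sided Kolmogorov–Smirnov. Two
  reference conventions are provided: against all genes (`"all"`, the
  figure-legend convention; D = 0 when the set is all genes, but the
  set⊂reference overlap makes null p-values conservative) and against
  the complement (`"complement"`, disjoint samples, exactly calibrated
  null). The calibration test in the suite uses the complement form,
  because uniformity of null p-values is a property only that form has.

# Clonal overlap

Cells sharing an identical multiset of (chain type, CDR3 nucleotide
sequence) pairs form one clonotype — the strictest reading of
"1–3 matching chains". A `match_mode = "any-chain"` flag implements the
laxer transitive single-chain merge; neither is asserted to be the
vendor caller's exact semantics, which is why both exist. Phenotype
overlap is the Jaccard index of clonotype-id sets, pooled and per mouse.
The Mantel test correlates the off-diagonal upper triangles of two
overlap matrices, permuting one matrix's labels jointly on rows and
columns; with ≤ 8 labels all $n!$ permutations are enumerated (exact
p; resolution $1/n!$), otherwise 9,999 random permutations with the
$+1$ correction. The test is one-sided (greater), matching the
directional question "is clonal structure reproduced", the sidedness
being otherwise unstated.

# The synthetic-data generator

One global seed fans out to fixed per-component streams
(`seed*97 + offset`), so adding a component never perturbs another's
draws and every output is byte-identical across reruns. Defaults encode
the emulated study design: 3 populations × 3 replicates; 300 latent
loci with 10% two-summit loci (chosen so that ~82% of source peaks fall
in fully-overlapping clusters, the share reported for the emulated
design); 40 motif groups with three planted effects
$\beta = (+0.8, +0.5, -0.8)$ and Gaussian log2FC noise sd 0.5; 700
genes in 7 archetypes under negative-binomial noise (dispersion 0.3) —
archetypes are equally spaced directions in the centered 3-population
profile plane, because per-gene Z-scoring identifies a 3-point profile
only up to location and scale; 600 cells with program structure aligned
to bulk clusters; 3 mice × 4 phenotypes × 150 clones with a planted
pairwise Jaccard matrix (one strong pair at 0.5, one at 0.2, background
0.05).

Motif instances are planted as the PWM *consensus word* at
collision-free offsets on either strand. A per-position sample would
leave a substantial fraction of planted instances below the exact
$P < 10^{-4}$ scan threshold (for sharp 8-mers, single-mismatch words
fall outside the $10^{-4}$ tail), making planted occupancy — the ground
truth of the design matrix — ill-defined.

Clonotype sharing is realized by a deterministic pairwise allocation:
for target Jaccard $J$ between phenotypes of $C$ clones each,
$s = \operatorname{round}(J \cdot 2C/(1+J))$ clones belong to exactly
that pair, the rest are private, so realized pairwise overlap matches
the target by construction. Clones belonging to three or more
phenotypes are not modeled.

Adjusted p-values in the simulated differential tables are a rank-based
stand-in (top quantile by |log2FC| gets small padj); negative-binomial
differential testing itself is deliberately out of the generator's
scope.

**What passing tests do and do not show.** The generator realizes
exactly the additive, independent-peak, i.i.d.-background world the
model assumes. Passing the planted-recovery tests shows the estimator,
significance calls and Δcor attribution are correct *under the model*;
it does not show robustness to the ways real chromatin violates it —
correlated motif co-occurrence, GC and repeat structure in backgrounds,
count-based noise in accessibility, batch structure. The oracle and
calibration tests (union-find clustering, exhaustive $4^L$ score
enumeration, combinatorial hypergeometric tails, exact Mantel
enumeration, null-uniform p-values) are unconditional.

# Problem sizes

The test suite and acceptance script run at sizes chosen to make every
property measurable with comfortable margins on a single core: 200
random peak sets of up to 200 peaks for the clustering oracle; 50 PWMs
of length ≤ 8 against exhaustive $4^L$ enumeration; planted ridge
recovery at 5,000 peaks × 40 groups over 20 seeds; the full
hypergeometric domain $m + n \le 20$; 200-replicate calibration runs;
1,000 random set pairs for the Jaccard identities. The end-to-end
pipeline default (300 loci, 40 groups, 700 genes, 600 cells, 1,800
clones across 3 mice) runs in well under a minute.

# Known limitations

* The Cule-style λ selection and p-values are a documented
  interpretation of a semi-automatic estimator, not a bit-exact port;
  different candidate rules can pick different λ on near-flat PRESS
  profiles (coefficients are insensitive to this in the tested regimes).
* The motif-similarity surrogate is not an E-value and should not be
  compared across catalogs; supply a real similarity table when one is
  available.
* Binary motif presence discards dosage and position; motifs whose
  effect depends on either are attenuated by design.
* Δcor is uninformative at subsets where a motif's presence is constant
  (see above); choose subsets with mixed motif content.
* The generator's clonal model has no clone-size structure beyond 1–3
  cells per phenotype and no cross-mouse shared clones; Mantel
  reproducibility across simulated mice reflects the shared *structure*,
  not shared clones.
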