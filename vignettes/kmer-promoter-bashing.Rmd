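---
title: "In silico promoter bashing with k-mers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico promoter bashing with k-mers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kmerbash` links promoter sequence variation to gene expression variation
across a pan-genome. Its unit of comparison is the *pangene*: the set of
gene models across accessions that share a locus. Within a pangene, the
promoter alleles differ by substitutions, short indels and structural
variants (SVs), and the member genes differ in expression. The package asks
which short sequences (k-mers) in those promoters drive the expression
differences, without ever aligning promoters to a reference.

# The regression model

Each promoter is decomposed into its k-mers (stride-1 windows, forward
strand of the oriented promoter, `N`-containing windows skipped). Unique
k-mers are sorted by abundance (ties broken lexicographically) and greedily
clustered: a k-mer joins the earliest-founded cluster whose representative
is within Hamming distance 1, otherwise it founds a new cluster. For
equal-length words this one-substitution rule is what an identity threshold
of $1-1/k$ permits, and doing it greedily over a deterministic ordering
makes the clustering reproducible bit-for-bit. Note the membership test is
against the representative only: a k-mer two substitutions from the
representative founds its own cluster even if it is one substitution from
another member. Clusters present in no more than 1% of promoters are
dropped; the survivors form the count matrix $X$, with $X_{ij}$ the number
of occurrences (overlaps included) of cluster $j$'s members in promoter
$i$.

Expression is modelled jointly across all genes and clusters:

$$ y = C\alpha + X\beta + \varepsilon,\qquad
   \varepsilon \sim N(0, \delta_e^2 I) $$

with a spike-and-slab prior on each cluster effect:

$$ \beta_j \sim (1-\gamma_j)\,N(0,\delta_0^2) + \gamma_j\,N(0,\delta_1^2),
   \qquad \gamma_j \sim \mathrm{Bernoulli}(\pi) $$

$$ \pi \sim \mathrm{Beta}(a_\pi, b_\pi),\quad
   \delta_1^{-2} \sim \Gamma(a_1, b_1),\quad
   \delta_e^{-2} \sim \Gamma(a_e, b_e). $$

The spike variance is fixed from the data as
$\delta_0^2 = q\,\mathrm{Var}(y) / \sum_j \mathrm{Var}(X_{\cdot j})$ with
$q = 0.05$ by default: if every column carried a background effect of this
size, background effects would jointly explain a fraction $q$ of the
expression variance. Effects are *per occurrence* of the sequence, so $X$
is deliberately not standardized.

## Gibbs sampler

Inference is by Gibbs sampling (`fit_bvs()`). Per sweep, each column's
$(\gamma_j, \beta_j)$ is updated jointly — $\gamma_j$ drawn with $\beta_j$
integrated out under the two-component prior, then $\beta_j$ from its
conjugate normal conditional. A plain conditional-$\gamma$ update mixes
poorly when the spike is narrow; the joint update does not. Covariate
effects $\alpha$ get a flat prior and a normal conditional; when $C$ is a
one-hot indicator design (the default per-pangene baselines), the update
reduces to per-group means and costs $O(n)$. $\pi$, $\delta_1^2$ and
$\delta_e^2$ follow their conjugate conditionals. Columns are scanned in
ascending index order (a random-scan option exists); all draws use R's RNG
stream, so a seed fixes the fit exactly. Normal deviates come from a
Box-Muller transform over that stream rather than inversion, purely for
speed.

The per-cluster posterior inclusion probability is the mean of retained
$\gamma_j$ draws. Selection uses the Bayesian local FDR: for each
candidate PIP threshold the estimated FDR of the selected set is the mean
of $1-\mathrm{PIP}$ over it, and the largest set with estimated FDR at or
below the target (default 0.1) is reported. Convergence is monitored with
Geweke z-scores (first 10% vs last 50% of the chain, batch-means
variances, 10 batches per segment) on $\log\delta_e^2$, $\pi$ and the
model size.

Hyperparameter defaults ($a_\pi=b_\pi=1$, all Gamma shapes/rates 0.01,
10000 iterations, 5000 burn-in, thinning 5) are package choices — vague
priors and a schedule long enough for the Geweke checks to pass on the
bundled fixtures. Both the unconditional posterior-mean effect and the
slab-conditional mean are reported, since either may be wanted as "the"
effect size.

# Functional-site filtering

A selected cluster's global effect averages over all its occurrences,
functional or not. `filter_functional_sites()` therefore regresses
expression on occurrence count *within each pangene* where the cluster
occurs with varying counts (at least 3 genes), adjusts the p-values by
Benjamini-Hochberg across all tested (cluster, pangene) pairs, and retains
pairs with $q < 0.05$ whose slope agrees in sign with the cluster's global
effect. BH is applied globally rather than per cluster — the conservative
single-family reading; a per-cluster option exists. Untestable pairs
(constant counts, fewer than 3 genes) are excluded from the family rather
than counted as tests.

# Promoter variability metrics and hv selection

Promoter similarity between two alleles is the number of distinct shared
31-mers — for 2 kb windows the score lives on $[0, 1970]$ and its log2 on
$[0, 10.94]$. A pangene's similarity is the mean over all unordered pairs,
reported as log2 of the mean with a mean of 0 mapped to 0 (the scale's
floor). Expression variability is $\log_{10}\mathrm{CV}^2$ of the members'
$\log_2(\mathrm{TPM}+1)$ values (sample SD; clamped at $-6$ for invariant
pangenes; pangenes with zero mean flagged silent). Because CV² falls with
mean expression, the expected value at each pangene's mean expression —
a centred running median over pangenes ordered by mean expression, window
`max(101, 1%)` of the pangene count, shrinking at the edges — is
subtracted. Highly variable (hv) pangenes are those in the lowest
`top_fraction` quantile of log2 similarity *and* the highest quantile of
normalized variability, after dropping pangenes with fewer than 6 members
or mean expression below 1. Quantiles use linear interpolation (type 7)
with inclusive comparisons.

Two readings of "log2 similarity" exist (log2 of the mean pair score vs
mean of log2 scores); the package uses log2 of the mean, which keeps the
stated 0-10.94 range exact. CV is computed on one value per gene.

# Choosing k by cross-validation

`cv_r2()` evaluates candidate k-mer sizes by 10-fold cross-validation
under three splitting schemes: by gene (rows dealt round-robin), by
pangene, and by accession (groups dealt whole, so no group spans train and
test). Clustering and the prevalence filter are re-derived inside each
training fold; held-out promoters are projected onto the training clusters
with the same Hamming-1 rule, unseen k-mers contributing zero. Per-fold
$R^2$ is the squared Pearson correlation between predicted and observed
expression — robust to fold-specific calibration offsets; a
$1-\mathrm{SSE}/\mathrm{SST}$ option exists. The selected k is the argmax
of mean $R^2$, ties to the smaller k. CV fits use a reduced MCMC schedule
(default 3000 iterations) since only posterior means enter the prediction.

# Motif enrichment

Cluster PWMs are position-wise base counts of member k-mers weighted by
their pan-genome frequencies, plus a pseudocount. Scanning uses the PWM
log-odds against a 0-order background with an *exact* p-value threshold:
the null score distribution of a random w-mer is computed by dynamic
programming over an integer-discretized score grid (bin width = score
range / 10000), and the threshold is the smallest score with tail
probability at or below the target (default $10^{-4}$). K-mers are scanned
on both strands (TF binding is strand-agnostic, unlike the forward-only
counting of the association step, which follows the promoter FASTA as
written). Library enrichment of the significant clusters uses a
permutation null — equal-size draws from the full model cluster set —
with the $+1$-corrected empirical p-value $(1 + \#\{null \ge obs\})/(1 +
n_{iter})$. Peak-overlap enrichment maps every occurrence back to genome
coordinates (mirrored arithmetic on the minus strand), computes per-cluster
fractions of occurrences intersecting a peak (any shared base, half-open
intervals), bins clusters at 20% (strictly greater = high-confidence), and
reports the fold enrichment of significant vs all model clusters with a
percentile bootstrap CI resampling clusters.

# The synthetic pan-genome generator

`simulate_pangenome()` emulates the study conditions the pipeline is built
for: 26 accessions, 300 pangenes, 2 kb promoters by default. Each pangene
descends from one uniform-random ancestral promoter, mutated independently
per accession: substitutions at 0.01/bp, short indels at 0.002/bp
(geometric lengths, mean 3), and background SV insertions of 50-900 bp
with probability 0.15 per allele. Five planted motif k-mers (default width
11) carry effects of ±2 log2 units per occurrence; each motif occurs in
15% of pangenes, in half of those pangenes' accessions. Half the motifs
ride inside a dedicated SV insertion — presence/absence coincides with the
SV, the key scenario for alignment-free discovery — and half replace bases
of the ancestral context in carriers only. Pangene baselines are
$N(2, 1)$ on the $\log_2(\mathrm{TPM}+1)$ scale and are absorbed by
per-pangene covariates (or centering) at fit time; the residual SD of 0.7
puts the planted-signal fraction of the within-pangene variance near 0.6.
Expression is generated exactly as $y_i = \mu_{g(i)} + \sum_j c_{ij}
\beta_j + \varepsilon_i$ with the same window-counting rule the model
uses.

The mutation model is intentionally naive — iid substitutions, no
selection, no phylogeny, uniform base composition — because the fixtures
test the inference, not molecular evolution. Real promoters are more
repetitive and more biased, which *increases* k-mer sharing across
pangenes; passing tests on these fixtures demonstrates the machinery, not
performance on any particular genome.

## Echo clusters and ground-truth attribution

A planted motif never produces just one informative cluster. The windows
overlapping the insertion junction, shifted by 1..k-1 bases, differ across
carriers only in their few junction bases; those variants are Hamming-1
siblings and aggregate into "echo" clusters whose counts are nearly
perfectly collinear with the motif's own column. The posterior then splits
inclusion across the family — the planted k-mer's own cluster can have
PIP near 0 while its one-shift echo has PIP 1. Any k-mer association
method has this structure. Ground-truth evaluation therefore credits a
selected cluster to a motif when its representative aligns to the motif
with at most one mismatch over at least eight bases
(`attribute_to_motifs()`); the thresholds follow from the construction
(echoes match exactly over their full overlap) rather than from tuning.

## Known limitation: chance-correlation selections

With tens of thousands of prevalence-filtered clusters and a few thousand
genes, one to three truly null columns per run reach a sample correlation
with expression around four standard errors simply by order statistics.
The adaptive slab assigns such columns moderate posterior inclusion
(PIP 0.4-0.9), and the local-FDR rule admits them because the many PIP~1
planted/echo clusters dilute the selection's average $1-\mathrm{PIP}$.
The realized false fraction per run is therefore often 10-30% even though
the estimated FDR of the selected set is below 0.1. Longer chains shrink
but do not eliminate these selections; they are a property of the
posterior at this scale, not a sampling artifact. Practically this is why
the pipeline does not stop at selection: the per-pangene functional-site
filter and the orthogonal motif/peak enrichment steps exist to separate
such statistical passengers from genuine regulatory sites.

## Why the k-selection fixture plants diverged instances

With every carrier holding the identical consensus k-mer, the windows one
base wider than the motif (motif + one junction base) fall into four
variants that are Hamming-1 siblings; they aggregate into one cluster that
marks the carriers exactly as well as the motif itself, so cross-validated
$R^2$ is flat between $k=w$ and $k=w+1$ and the argmax is decided by
noise. Real TF sites are families of near-identical instances, so the
k-selection fixture plants a one-substitution variant in half the carrier
pangenes (`motif_divergence = 0.5`). At $k=w$ the variant instances still
join the consensus cluster (they are Hamming-1 from it); at $k=w+1$ the
variant junctions are Hamming-2 from the consensus junctions, fragment
below the prevalence filter, and only the consensus half survives —
giving the genuine $R^2$ peak at the planted width that the k-selection
procedure is supposed to find.

# Study sizes used by the bundled checks

The test suite and `scripts/acceptance.R` run the full chain at sizes
chosen for a single-CPU run: recovery studies use the default 300
pangenes x 26 accessions with 1 kb promoters and an MCMC schedule of
4000 iterations (1600 burn-in) — the shortest schedule whose Geweke
diagnostics pass on these fixtures; null-calibration replicates use 400
genes x 60 clusters; the k-selection study uses 60 pangenes x 8 accessions
with 300 bp promoters and width-8 motifs. The exact-posterior cross-check
enumerates all inclusion patterns at p <= 8, n = 20 with point-mass
hyperpriors, and the PWM scanner is compared against exhaustive
enumeration of all 4^w words at widths up to 8.

# Numerical and edge-case conventions

* Coordinates are 0-based half-open everywhere internally; GFF3 is
  converted on read, BED passes through unchanged. The transcription start
  is the annotated gene start (+) or end (-) when no transcript-level TSS
  exists; windows truncated at contig edges are kept.
* `N` bases survive extraction; every k-mer window containing one is
  skipped, in counting and in similarity alike.
* Reverse complementation of counting is off by default (the promoter
  FASTA is already oriented); a flag merges reverse complements where
  wanted.
* Ties in k-mer ordering break lexicographically; cluster ids are founding
  order; rows of the count matrix are sorted by gene id, so input order
  never changes a result.
* `log2(0)` similarity and zero-variance CV are clamped (0 and -6) rather
  than propagated as infinities; silent pangenes give `NA` and are
  excluded from hv selection.
* Promoter windows overlapping an upstream gene are neither masked nor
  truncated; nothing in the pipeline depends on them being intergenic.
* The count matrix is stored sparse; the sampler keeps a compact internal
  copy (16-bit row indices where the row count allows, single-precision
  values) because the sweep is memory-bandwidth-bound. Accumulations stay
  in double precision.
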