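---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
statistic assumes, which tunable parameters matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely open
and a choice had to be made. It states no empirical result that the test
suite does not itself compute.

# Quality control and marker detection

Cells are retained when they carry at least `min_umis` (default 1000)
transcripts over at least `min_genes` (default 200) detected genes, and when
at most `max_mito_ribo_fraction` (default 0.10, strict `>` removal) of their
counts fall on mitochondrial or ribosomal genes. Genes are retained when
expressed in strictly more than `min_cells_per_gene` (default 3) *retained*
cells — the gene filter is evaluated after the cell filter, because
prevalence is a property of the analyzed cell population. Consequences worth
knowing: filtering is idempotent, and removing one failing cell can change
another gene's retention only through prevalence, never another cell's
status. Whether the 10% rule applies to the mitochondrial+ribosomal *sum*
or to each fraction separately is not fixed by convention; the sum is the
default, `mito_ribo_rule = "separate"` is the alternative. Mitochondrial and
ribosomal genes are recognized by symbol prefix ("MT-", "RPS"/"RPL") with an
explicit `gene_flags` override, since no fixed gene list is universal across
annotations.

Immunophenotype gating (`gate_malignant()`) calls a cell malignant when
every positive-gate gene has a raw count above zero and every negative-gate
gene is at zero. Surface-marker gating has no canonical numeric cutoff at
the transcript level, so count-positivity is the default and a
normalized-expression threshold is the configurable alternative.

Marker detection is a per-gene, one-vs-rest two-sided Wilcoxon rank-sum test
on log-CP10k expression (counts per 10k, `log1p`), the dominant
normalization of the droplet toolchain; the scheme matters only through
ranks within the tested vector for the p-value, but it also defines
`logFC = log2(mean + 1) - log2(mean + 1)` in base 2 with pseudocount 1, so
that conventional thresholds such as `logFC > 1` keep their usual meaning.
When the pooled sample is small (<= 25 observations) the exact permutation
null of the rank sum is computed by a generating-function convolution over
doubled mid-ranks; larger samples use the normal approximation with tie and
continuity corrections. Benjamini–Hochberg adjustment is applied within each
cluster's tested gene list.

# Rank-based signature scoring

The single-sample score is a classic (unweighted) Kolmogorov–Smirnov running
sum, not an expression-weighted enrichment statistic: genes are walked from
highest to lowest expression, the sum gains `1/|S|` at the `|S|` measured
signature genes and loses `1/(G-|S|)` at the other `G-|S|` genes, and the
score is the deviation of maximal magnitude, signed so that positive means
enrichment among highly expressed genes. The walk depends only on
within-unit ranks, so any strictly monotone transform of a unit's expression
leaves the raw score unchanged — this is what lets the same engine score
UMI-count cells and log-scaled chip cohorts. Ties are broken by gene name so
the walk is deterministic. Whether the deviation should be one-sided is
genuinely open; the signed two-sided maximum is the default and is not
silently changed.

A kernel-density preprocessing step is available (`kde_filter = TRUE`,
Silverman bandwidth): it discards genes below the first antimode of the
unit's expression density, treating the zero-inflation mode as unmeasured.
It is interpreted as a diagnostic filter, never as something that reorders
ranks, because the operative statistic is explicitly rank-based; it is off
by default.

The stemness index applies a pre-trained (gene, weight) vector: the raw
index is the Spearman correlation between a unit's expression of the
weighted genes and the weights, min–max scaled across the cohort. Training
such a vector (one-class logistic regression over stem-cell atlases) is out
of scope; a clearly-labelled synthetic example vector ships in
`inst/extdata/stemness_weights_synthetic.tsv`.

Cohort min–max scaling maps raw scores to [0, 1]; a degenerate cohort (all
raw scores equal) is reported as 0.5 everywhere with a warning rather than
as an error, so downstream class assignment stays total.

# The three-detector communication framework

All three detectors share per-cluster profiles: mean log-CP10k expression,
detection fraction, a "highly expressed" set, and the DEG set
(`p_adj < 0.05`, `logFC > 0.25` by default — the DEG logFC gate is the
conventional marker threshold, distinct from the stricter `logFC > 1` used
for origin signatures). "Highly expressed" defaults to the top decile of a
cluster's mean expression; a detection-fraction variant (>= 10% of cells)
and the union are available via `high_gate`, but the quantile rule is the
default because the fraction rule admits most measured genes and makes the
network-mapping universe nearly saturated.

**Detector 1 (joint expression).** A pair is testable only when the ligand
is detected in at least 10% of source cells and every receptor subunit in at
least 10% of target cells; a multi-subunit receptor is carried by its
limiting (minimum-expression) subunit. The statistic is mean ligand
expression in the source plus mean receptor expression in the target; the
null permutes cluster labels, `p = (1 + #{null >= obs}) / (n_perm + 1)`.

**Detector 2 (DEG matching).** Deterministic: an event is emitted when the
ligand is in the source's DEG-or-high list, the receptor complex in the
target's, and the pair is in the database; ranked by `mean_strength` with a
lexicographic tie-break.

**Detector 3 (hypergeometric / randomized networks).** Per ordered cluster
pair, with N measured database pairs, K ligand-positive, n
receptor-positive and k jointly positive, the analytic gate is the
upper-tail hypergeometric `P(X >= k)`; the empirical gate compares k to its
distribution over degree-preserving rewirings of the bipartite
ligand–receptor graph (double-edge swaps, `10 x |pairs|` attempts per
replicate plus a parity jitter that keeps tiny graphs from being trapped in
their starting state; duplicate edges forbidden; 1000 replicates by
default). What exactly plays N, K, n, k was not fixed by the framework's
published description; this mapping is one coherent reading and is isolated
in a single function so alternatives can be swapped. Likewise "randomized
networks" is interpreted as degree-preserving rewiring — the standard null
that preserves the marginals a hypergeometric comparison needs. Both gates
must pass (the conservative reading); the pair's k mapped events are then
emitted. Per-pair (not per-event) empirical counting is used.

Benjamini–Hochberg correction within each detector is on by default
(`bh = FALSE` restores raw gating); directed cluster pairs including
self-pairs (autocrine) are always enumerated. The consensus rule is purely
cardinal: an event is high-confidence iff at least two of the three
detectors report it, whichever two they are.

# Origin typing and heterogeneity

Origin signatures are the type-I / type-IX cluster markers with strict
`logFC > 1` and `p_adj < 0.05`. Abundances come from the same rank/KS
scorer applied to sample-level profiles; `dominance = abundance_I -
abundance_IX` exactly. "Positive" has no published numeric definition, so
the default positivity threshold is the per-signature cohort median — a
scale-free, reproducible split under which classes are invariant to any
strictly monotone transform applied jointly to a signature's cohort
abundances; `zero` and `quantile` rules are provided. The four classes
(double positive, double negative, I-only, IX-only) always partition the
cohort.

The Pi matrix is `-log10(p_adj) x logFC` per gene and cluster, with `p_adj`
floored at 1e-300 before the log so entries stay finite; genes absent from
a cluster's table contribute 0. The self-organizing map is an online
Kohonen network (default 10 x 10 grid, 100 epochs, learning rate decaying
linearly 0.5 -> 0.01, Gaussian neighbourhood with linearly shrinking
radius), sized for the hundreds-to-thousands of genes a marker run yields.
Because online training depends on presentation order, the implementation
canonicalizes the training order (lexicographic by row values) so that
assignments are exactly invariant under permutation of the input genes;
determinism under the seed then gives full reproducibility.

The diversity score embeds all malignant cells jointly by PCA of log-CP10k
expression and keeps the top `d = 30` components (reduced with a warning
when fewer exist — the original eigenvalue-significance screen is unnamed
in its source, so the fixed-d rule replaces it). A patient's score is the
mean Euclidean distance of their cells to their centroid in that space:
zero for identical cells, translation-invariant, linear under uniform
scaling, unchanged by duplicating cells, and computed only for patients
with at least two cells. The mean-distance-to-centroid form is one of
several published "diversity" variants; it is isolated in one function.

# Variant burden

TMB is the count of distinct (chrom, pos, ref, alt) keys per (sample,
level), divided by `genome_size_mb`. No default genome size is assumed —
whether a study's denominator was callable-region or whole-genome megabases
is a per-dataset fact, so it is a required configuration value. Indels
count toward TMB but are excluded from the six-class pyrimidine-centric
substitution spectrum, where purine-reference records collapse by reverse
complement (G>A -> C>T, A>G -> T>C, ...). The sharing partition calls a
variant origin-stage when present in *every* subclone of a sample and
evolution-stage otherwise; the two buckets are disjoint and cover every
subclone-observed key exactly once.

# The synthetic-data generator

`simulate_counts()` draws UMI counts NB(mu, size = 1/dispersion) — variance
`mu + dispersion * mu^2`, one dispersion shared across genes, which is
sufficient for the rank-based statistics downstream. Per-gene baseline
means are log-normal around `baseline_mean` (sdlog 0.5 by default) so that
expression ranks vary across genes; without this, "top decile expressed"
would be an arbitrary tie-break rather than a meaningful random subset, and
the crosstalk calibration test would be vacuous. Cluster-specific marker
multipliers, planted ligand/receptor fold-ups, and per-sample origin
gradients multiply these means. Mitochondrial counts are injected by
designating a gene block "MT-" and scaling its means so each cell hits its
cluster's target fraction in expectation. One global seed feeds per-stage
derived substreams, so counts and variants can be re-generated
independently.

What the generator does **not** emulate: doublets, batch effects, ambient
RNA, gene-length/GC bias, spliced/unspliced layers, or gene–gene
correlation beyond cluster structure. A green planted-recovery test
therefore establishes that the statistics behave correctly under their own
model assumptions — not that they are robust to every artifact of real
droplet data.

`simulate_variants()` plants `n_shared` variants in every subclone and
`n_private` per subclone, with bulk defined as the union of subclone
records, and substitution classes drawn from a configurable
pyrimidine-centric mixture reported on a random strand (so the
reverse-complement collapse is genuinely exercised).

# Numerical choices and degenerate inputs

* Exact rank-sum path for pooled n <= 25; normal approximation with
  continuity and tie corrections beyond.
* Permutation and network p-values use the +1 correction and can never be
  zero; `p_empirical >= 1/(R+1)`.
* `p_adj` floor 1e-300 in the Pi matrix; TMB identity `tmb * mb = n` holds
  to machine precision.
* Empty QC results warn instead of erroring; single-cell patients get `NA`
  diversity; degenerate cohorts scale to 0.5 with a warning; a saturated
  ligand–receptor graph is returned unrandomized with a warning.
* All set-like readers are order-insensitive; matrices are indexed by
  identifier, never file order.

# Pipeline and configuration

`run_pipeline()` drives the stages behind one configuration object,
readable from JSON (`read_pipeline_config()`); stage dependencies are
enforced (markers before crosstalk/origin/heterogeneity), every stage
writes TSVs plus a manifest with input digests, and identical
configurations reproduce identical outputs, stochastic stages included.
JSON rather than YAML keeps the dependency footprint to jsonlite, which the
package already uses for the manifest. The command-line wrapper lives at
`inst/cli/clonescape.R`.

# Known limitations

* Cluster labels are an input: graph-based clustering, embedding for
  visualization, batch integration, pseudotime, velocity and CNV/SV calling
  are all out of scope.
* The hypergeometric universe mapping and the "random walk network" reading
  are documented interpretations, each isolated behind one function.
* The stemness weight vector is applied, never trained.
* The rank/KS scorer is a single-deviation statistic; it is not an exact
  re-implementation of GSVA or ssGSEA and will differ from them on the same
  inputs.
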