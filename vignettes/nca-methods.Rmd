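---
title: "Reconstructing dynamic regulatory networks with constrained matrix decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing dynamic regulatory networks with constrained matrix decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncanet)
```

## The model

Developmental expression time courses mix two things we would like to
separate: the hidden, condition-dependent *activity* of each transcription
factor (TF) protein, and the *control strength* with which that activity
drives each target gene. Under the standard log-linear (Hill-cooperation)
picture of transcription, a gene's expression ratio against a control stage
is a product of TF activity ratios raised to their control strengths,

$$\frac{E_i(t)}{E_i(0)} \;=\; \prod_{j=1}^{L}
  \left(\frac{\mathrm{TFA}_j(t)}{\mathrm{TFA}_j(0)}\right)^{\,CS_{ij}},$$

which becomes linear after taking log2:
$[E] = [S][A]$, with $[E]$ the $N \times M$ matrix of log2 expression ratios
(genes by stages), $[S]$ the $N \times L$ control strengths and $[A]$ the
$L \times M$ log2 TF activity ratios. Network component analysis (NCA)
estimates both factors by solving

$$\min \lVert [E] - [S][A] \rVert_F
  \quad \text{subject to } S \in Z_0,$$

where $Z_0$ is a fixed sparsity pattern: the prior knowledge of *which* TF
may regulate *which* gene. Unlike PCA or ICA, no orthogonality or
independence is assumed; the constraint set alone makes the factorization
identifiable.

## Identifiability and the gauge

The constrained factorization has a unique solution only up to a diagonal
rescaling ($[S][A] = [S][X][X^{-1}][A]$ for any nonsingular diagonal $[X]$;
only diagonal matrices preserve $Z_0$), and only when the topology satisfies
three criteria, checked by `check_identifiability()`:

1. the support pattern has full column rank $L$;
2. deleting any TF together with every gene it regulates leaves a pattern of
   full column rank $L-1$;
3. $L \le M$, so the activity matrix can have full row rank.

Ranks are *generic*: the pattern is filled with random nonzero values
(three fillings by default, seeded) and the maximal QR rank is taken. This
is the standard cheap surrogate for structural rank — a pattern that is
full-rank for one generic filling is full-rank for almost all of them. A
subtlety worth recording: two TFs with identical *support* columns are
generically full column rank (criterion 1 passes), but they fail
criterion 2, because removing either TF removes the other's entire support.
`reduce_to_identifiable()` repairs a failing prior greedily, removing the TF
whose deletion most reduces the count of violations (ties: fewest targets,
then lexicographic identifier) and dropping orphaned genes, until the
checker passes; the removal log is attached to the result.

The reported solution fixes the gauge completely. Under the default
`"control-zero"` convention each activity row has its control-stage entry at
0 (this shift is numerically exact, because the control column of $[E]$ is
zero and the activity step is unrestricted least squares), each TF's sign is
chosen so its strength column correlates nonnegatively with the prior's
correlation-valued strengths, and each strength column is scaled to unit
Euclidean norm. `"unit-activity-norm"` instead puts the unit norm on
activity rows. Both are idempotent, leave $S A$ unchanged to numerical
precision, and map any diagonal re-gauging of a solution back to the same
canonical form — which is what makes fits comparable across runs,
bootstrap draws and ground truth.

## The solver

`nca()` uses alternating least squares (ALS). With $A$ fixed, each gene's
supported strengths solve a small least-squares system in its own row of
$E$; with $S$ fixed, $A$ is the unrestricted least-squares solution. Both
half-steps are exact minimizers, so the objective trajectory is
nonincreasing — asserted in the test suite on every run. Convergence is
declared when the relative objective change drops below `tol` (default
1e-8) or the objective falls below $10^{-13}\lVert E\rVert_F$ (the
relative-change rule is meaningless once the fit is exact to machine
precision); `max_iter` (default 1000) caps each run.

ALS can stall in local minima, so the fit is restarted `n_restarts` times
(default 10) and the best final objective wins. Restart 1 is deterministic
and starts from the prior's signed correlations — the coexpression starting
point — so the returned fit can never be worse than the correlation-seeded
solution; the other restarts draw standard-normal activity matrices from
the seed. On identifiable synthetic data this recovers activities and
strengths essentially exactly without noise, and to activity correlations
above 0.9 at log2 noise of 0.1 (both checked in `test-acceptance.R` at
$N=100$, $L=10$, $M=20$).

Degenerate inputs are handled conservatively: a rank-deficient per-gene
subproblem gets zero coefficients for the unidentified directions (QR with
pivoting), a non-identifiable prior is refused before any fitting with the
full diagnostic attached, and an all-zero activity row or strength column
stops normalization with an error rather than silently rescaling by zero.

## The coexpression prior

With curated TF–target interactions scarce, the prior connectivity is built
from the expression data itself. After reducing each stage to log2 ratios
against the control stage (`compute_log_ratios()`) and keeping genes with
linear fold change above 1.6 somewhere in the course (`filter_degs()`;
interpreted as $|\log_2 FC| > \log_2 1.6$, with the literal log2 reading one
flag away), `build_prior()` admits a TF–gene edge when two conditions hold
at once: the absolute Pearson correlation of the two profiles exceeds
`r_threshold` (default 0.9), and the two genes co-occur in one cluster when
the complete-linkage dendrogram on the $1-|r|$ distance is cut at
`cut_height` (default 0.1 — the same scale as the correlation rule, so the
defaults are mutually consistent). The sub-tree condition is what makes the
prior stricter than a bare correlation screen: a gene can correlate with a
TF above threshold yet sit in a different cluster, and is then excluded.
Anticorrelated pairs are admitted with negative strengths, since negative
correlation is read as repression; for the same reason the distance uses
$|r|$, not $r$. Edge signs in the final network likewise follow the sign of
the TF–target expression correlation, with an exact-zero correlation
falling back to the fitted strength's sign (logged as a tie-break).

## What the synthetic generator emulates — and what it does not

`simulate_truth()` provides the ground truth every downstream stage is
tested against. Its defaults describe a staged developmental course of the
kind the method targets: seven ordered stages (`UNM`, `BCP`, `TCP`, `MP`,
`HP`, `PT05`, `PT4`) with the mature-pollen-like stage `MP` as control, 100
target genes, 10 TFs with 3 regulators per gene, strengths of magnitude
0.5–0.95 with 30% repression, single-peaked activity trajectories of
amplitude 2 (log2 units) peaking at a random interior non-control stage,
and additive Gaussian noise on the log2 scale — the residual model implied
by a model that is linear in logs (multiplicative log-normal on the linear
scale). The noise level is a free choice (the generating model says nothing
about it); 0.1–0.2 log2 units is the scale of replicate scatter typical of
well-replicated microarray ratios. Noise is added to every stage except the
control: the control ratio is the control sample divided by itself, so its
log is identically zero, not noisy.

Each TF's own transcript is included as an autoregulated gene row (self
strength 1), because TFs *are* genes: the coexpression prior, the
edge-signing rule and the activity-vs-expression comparison all need TF
transcript profiles. Activity trajectories are statistical stand-ins
(smooth seeded bumps), not simulations of any real regulon; the generator
makes no attempt to mimic probe-level microarray artifacts, detection
calls, or cross-laboratory effects. Consequently, passing recovery tests
shows the estimator does its mathematical job under the stated model — it
does not show that real staged microarray data satisfy that model.

Topology generation is rejection sampling: draw a pattern, check criteria
1–2, retry up to 1000 times, and fail loudly — an infeasible request (for
example `edges_per_gene = n_tfs`, under which criterion 2 can never hold)
is better reported than silently repaired. Criterion 3 involves the stage
count, which the topology generator does not see; `simulate_truth()`
enforces it against the actual stage labels.

## Bootstrap stability, honestly stated

`nca_bootstrap()` resamples genes with replacement, refits each resample
(warm-started at the reference activities, single start), rejects draws
whose resampled support breaks identifiability, aligns each refit to the
reference gauge by a per-TF least-squares scalar — a convention-based
normalization would not do, since a unit-column-norm scale depends on which
genes a resample drew — and returns percentile intervals.

These intervals mean different things for the two factors. The activity
matrix is a global parameter averaged over genes, and resampling genes is a
consistent bootstrap for it: at the recovery-grade conditions the test
suite asserts that 95% intervals cover at least 90% of the true activity
values. Per-gene strengths are different: a
gene's own measurement noise is never redrawn when genes are resampled, so
a strength's bootstrap distribution reflects only the uncertainty
propagated from the activities and is too narrow as a confidence interval
for the true strength. The intervals are still useful as stability
diagnostics (how much a strength moves when the gene panel changes), and
that is how they should be read. This limitation is inherent to the
resampling scheme, not to its implementation.

## Motif census

`enumerate_subgraphs()` implements exhaustive non-redundant enumeration
(ESU) of connected induced subgraphs of sizes 3–5, with connectivity taken
on the underlying undirected graph and self-loops excluded (autoregulation
is a node attribute, not a subgraph edge). Classes are canonical adjacency
strings minimized over all $k!$ node permutations — brute force is exact
and cheap at $k \le 5$ (at most 120 permutations, cached per observed
pattern), and sidesteps the subtleties of refinement-based canonicalizers.
Signed classes (activation vs repression on each edge) are available behind
a flag; the default census is structural.

Significance comes from a degree-preserving null: repeated double-edge
switches (default $100 \times$ edge count attempts), each applied only if
it creates no self-loop and no duplicate edge, so in- and out-degree
sequences are preserved exactly on every draw; a graph with no legal switch
is returned unchanged, which makes the degenerate case (for example a
complete digraph) yield identical nulls, zero null standard deviation, and
honestly undefined z-scores. Empirical p-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{random}})$, so
$p = 0$ never occurs and the smallest attainable value is
$1/(n_{\text{random}}+1)$. The test suite checks the enumerator against
brute-force subset enumeration and an igraph-based canonicalizer, and the
switch-based null against igraph's independent rewiring on per-class means.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the scale the method is
characterized at in this package: recovery at $N=100$ genes, $L=10$ TFs,
$M=20$ stages (noiseless, and 10 seeds at noise 0.1); solver-vs-oracle
equivalence at $4 \times 2 \times 5$; 100 random instances for monotonicity
and support preservation; 100 random small priors for checker validation;
20 digraphs of up to 30 nodes for the enumeration oracle; and planted
feed-forward-loop detection with 1000 randomizations. The pipeline's
default motif census is $k = 3$ with 200 randomizations; exhaustive $k=5$
enumeration is exact but combinatorially heavy on hub-dominated networks,
so deeper censuses are an explicit opt-in via `motif_sizes`/`n_random`.

Other defaults worth knowing: all tie-breaks are deterministic (lowest
index, then lexicographic identifier); every random choice flows through a
single seed via a fixed derivation, so a pipeline rerun with the same
configuration is byte-identical; thresholds (1.6 fold change, 0.9 prior
correlation, 0.5 TF-pair coactivity) are conventional defaults and all
overridable in `pipeline_config()`.

## A short worked example

```{r example, eval = FALSE}
truth <- simulate_truth(n_genes = 60, n_tfs = 6, noise_sd = 0.1, seed = 1)
fit <- nca(truth$expression, truth$prior, seed = 1)
summary(fit)
plot(fit)                       # inferred activity trajectories per stage

net <- assemble_network(fit, truth$expression)
net
census <- motif_significance(net, k = 3, n_random = 200, seed = 1)
head(census)
```

## Known limitations

* The log-linear model assumes multiplicative TF cooperation; saturating,
  combinatorial-logic or chromatin-level regulation is outside it.
* The coexpression prior inherits all the usual caveats of correlation:
  indirect regulation and confounded coexpression enter the support, and
  the identifiability reduction decides which TFs survive — the removal
  log should be inspected, not trusted blindly.
* Missing values are rejected rather than imputed; detection calls
  ("expressed" flags) are expected from upstream or via a simple
  fold-change threshold.
* Strength bootstrap intervals are stability diagnostics, not calibrated
  confidence intervals (see above).
* TF–TF coactivity pairs are correlations of inferred activities, never
  claims of physical interaction.
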