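---
title: "Methods: state-specific GRNs for a bifurcating B cell fate decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-specific GRNs for a bifurcating B cell fate decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifurcGRN)
```

## The problem

Activated human B cells bifurcate into two fates: antibody-secreting
plasmablasts (PB) and germinal-center B cells (GCBC). Which transcription
factors (TFs) steer a cell toward one fate or the other is a question about
the underlying gene regulatory network (GRN): which TF regulates which gene,
with what sign and strength, in which cell state. bifurcGRN implements a
pipeline that assembles such networks from paired single-cell RNA and ATAC
(multiome) data, simulates TF knockouts on them, and tests clonal fate
statistics — together with a synthetic data generator that plants a known
network so that every stage can be validated against ground truth.

## Regulatory-potential models

The anchor of network assembly is a per-gene *regulatory potential* (RP)
model. For gene $g$ with candidate cis-regulatory elements (cCREs) $j$ at
signed TSS distances $d_j$, the per-cell RP is

$$\mathrm{RP}_{gc} = \sum_j w_j\, a_{jc}, \qquad
  w_j = \exp(-|d_j|/\ell_{\mathrm{side}(j)}),$$

where $a_{jc}$ is the accessibility count of peak $j$ in cell $c$ and
$\ell_{\mathrm{up}}, \ell_{\mathrm{down}}$ are upstream/downstream decay
lengths. Contributions are additive and decay exponentially with distance
from the TSS. Expression counts are modeled as
$y_{gc} \sim \mathrm{Poisson}\!\left(s_c\, e^{\alpha + \beta\,\mathrm{RP}_{gc}}\right)$
with library-size offset $s_c$.

Numerical choices:

* **Peak–gene window**: cCREs within ±100 kb of the TSS (nearest peak edge;
  0 if the peak spans the TSS), configurable. This spans the extent of
  typical displayed RP models while keeping fits local.
* **Decay grid**: $\ell$ is fitted by exhaustive search on a 12-point
  logarithmic grid from 500 bp to 100 kb per side (`decay_grid()`). A grid
  keeps the optimum exact and reproducible; the likelihood in $\ell$ is not
  concave, so continuous optimization could silently find local optima. At
  each grid pair, $(\alpha, \beta)$ is fitted by Poisson IRLS
  (`glm.fit`). Ties in the grid arg-max (within $10^{-9}$ log-likelihood)
  break toward larger $\ell$ — the smoother model.
* **Raw accessibility counts** enter the RP sum; the Poisson likelihood
  absorbs depth through the offset on the expression side.
* A gene whose linked peaks are all zero yields a flagged intercept-only
  model with $\beta = 0$.

## In-silico deletion (ISD)

A TF's influence on a gene is scored by deleting (hard-masking) the model
peaks that overlap the TF's binding regions by at least 1 bp, recomputing RP
from the remaining peaks with the decay lengths frozen, refitting only
$(\alpha,\beta)$, and taking the drop in log-likelihood. Freezing the decay
keeps scores comparable across TFs; hard deletion with refit is used because
it has an exact reduction oracle: deleting *every* peak must reproduce the
intercept-only fit, which the test suite checks to $10^{-8}$. The score is
exactly zero when nothing overlaps, and with several binding sets per TF the
maximum is retained with its provenance.

## Base network and state-specific networks

The TF×gene ISD matrix is binarized by a **global** top-5% cut: the
$k = \mathrm{round}(0.05 \times n_{\mathrm{TF}} n_{\mathrm{gene}})$ largest
scores across the whole matrix become links (ties break by score, then TF,
then gene, so output is deterministic). The cut is global rather than
per-TF because it makes the per-TF average exactly
$0.05 \times n_{\mathrm{gene}}$ — about 215 targets per TF at a
4,306-gene matrix — while letting well-supported TFs carry more links.
For TFs lacking ISD scores, co-accessibility links strictly above 0.8 are
added, restricted to modeled genes; they never overwrite ISD-sourced links.

Within each cell state, every gene is regressed on its candidate TFs with
**Bayesian ridge regression** (evidence approximation; hyperparameters by
MacKay fixed-point updates, intercept unpenalized via centering). Each edge
gets a weight, a posterior sd, and a two-sided normal-tail p-value. Round 1
fits all base-network candidates; edges with $p < 0.001$ are ranked
(ascending $p$, then descending $|w|$, then lexically) and capped at
10,000; round 2 refits each gene on its retained TFs only and provides the
final weights. When fewer than the cap pass the p filter, the filter wins:
the retained count is $\min(10000, \#\{p < 0.001\})$. p-values are raw
(no multiple-testing correction), matching the filter's definition as a
ranking device rather than an inferential claim.

TF importance per state is **eigenvector centrality** of the undirected
graph over TFs and genes weighted by $|w|$ (unsigned, so the adjacency is
nonnegative and the Perron vector is well-defined), computed by power
iteration to $10^{-10}$ with a diagonal shift that guarantees convergence on
bipartite graphs. Per-TF centralities are standardized across states and
clustered by seeded k-means (default $k = 6$, 50 restarts).

## In-silico knockouts and perturbation scoring

A TF knockout is simulated by setting its (log-normalized) expression to
zero and propagating through the state's weight matrix for `n_steps = 3`
rounds — primary, secondary, tertiary targets. After each step simulated
expression is clamped at zero and the TF re-clamped; the clamp prevents
negative expression and is applied because propagation is linear otherwise.
Cells in states without a fitted network get a zero shift.

The gene-space shift $\Delta X_c$ is embedded as a 2-D flow: transition
probabilities over the $k = 200$ nearest embedding neighbors are a softmax
(temperature 0.05) of the correlation between $\Delta X_c$ and each
neighbor's expression difference, and the cell's vector is the weighted mean
displacement minus the uniform-neighbor baseline. The differentiation flow
is the smoothed central-difference gradient of mean pseudotime on a 40×40
grid (Gaussian $\sigma$ = 1 bin, occupancy-masked). The per-cell
perturbation score is the dot product of the two vectors, and

$$\Delta\mathrm{PS} = \sum_{c \in \mathrm{GC}} \mathrm{PS}_c -
                      \sum_{c \in \mathrm{PB}} \mathrm{PS}_c,$$

positive when the knockout pushes cells toward the GC fate — the signature
of deleting a PB-promoting TF. The neighbor kernel is plumbing, not
biology; its parameters are exposed and the sign of $\Delta\mathrm{PS}$ is
insensitive to them over a wide range in our tests.

## Clonal fate concordance test

Clonotypes with ≥ 2 cells are classified PB-only / GC-only / bifurcated.
The null of fate–clone independence is simulated in two modes:

* **permutation** (default): fate labels are permuted across all cells,
  exactly conserving the clone-size multiset and marginal fate counts;
* **poisson**: clone sizes are redrawn as $1 + \mathrm{Poisson}(\hat\lambda)$
  with rates fitted per fate class, fates assigned i.i.d. at the observed
  marginal frequency, and cells subsampled to the observed count.

Both are provided because the source description mixes Poisson size
modeling with index shuffling; permutation is the default since it
conditions exactly on the observed margins. Per category,
$z = (\mathrm{obs} - \overline{\mathrm{sim}})/\mathrm{sd}(\mathrm{sim})$ and
$p = 2(1 - \Phi(|z|))$ — the normal approximation to the simulated null,
used verbatim rather than an empirical rank p. Degenerate null spreads
(sd = 0) report p = 1 when the observation equals the mean and 0 otherwise,
with a flag. Clone sizes are $1 + \mathrm{Poisson}$ so clones are never
empty while the tail stays Poisson-shaped.

## Composite-element scanning and target calling

The scanner does exact IUPAC-consensus matching on both strands
(S = C/G, N = any): EICE `GGAANNGAAA`, ISRE `GAAANNGAAA`, AP1 `TGASTCA`
(palindromic: scanned once), PRDM1 `GAAAGTGAAAGT`, a configurable ETS core.
AICE is a composite — an AP1 site and a `GAAA` half-site co-occurring with
a 0–4 bp gap in either order (the literature describes 0- and 4-bp spaced
variants; the range is configurable); PRDM1_IRF is an overlapping
PRDM1/ISRE pair. Consensus matching (not PWM scoring) is used because the
element definitions are consensus strings; minus-strand hits are reported
in plus-strand coordinates.

Knockout target genes are called by the replicate-concordance filter —
kept iff $|FC| > 1.25$ (strict, linear scale, i.e. $|\log_2 FC| >
\log_2 1.25$) and FDR ≤ 0.05 (inclusive) in *both* replicates with matching
sign — and then anchored to binding evidence: a DEG is a *direct target* of
a TF when at least one of its linked cCREs contains a seqlet of the TF's
motif family, and its RP score is the sum of the decay weights of those
seqlet-bearing cCREs. Set overlaps between target programs use two-sided
Fisher exact tests with a 0.5-continuity-corrected sample odds ratio and
BH correction across tested pairs.

## The synthetic data generator

`generate_true_grn()` plants the network: pro-PB and pro-GC TFs mutually
repress each other's target programs (the toggle motif of the fate
decision), housekeeping TFs bind inert decoy cCREs with zero planted
effect — giving in-silico deletion a planted null. `simulate_multiome()`
realizes it: TF activities are 4-parameter logistic profiles in pseudotime,
branch-specific after the branch point (default 0.4); peak counts are
Poisson with log-rate = basal + signed binding strength × activity; gene
counts are Poisson with log-rate = $\alpha + \beta\,\mathrm{RP} + \log s_c$
where RP uses the *planted* decay weights over *all* the gene's cCREs —
exactly the model the fitting stage assumes, so parameter-recovery tests
are interpretable. Counts are Poisson by default, with a negative-binomial
switch (`noise$nb_size`) for overdispersion robustness checks. The
embedding is analytic — (pseudotime, signed branch offset) plus Gaussian
noise — so the differentiation gradient has a closed form for oracle tests.
Clone sizes are $1 + \mathrm{Poisson}(\lambda)$ with a concordance dial
$\rho$: at $\rho = 1$ clones are single-fate, at $\rho = 0$ fates are
i.i.d.

What the generator does *not* emulate: droplet artifacts (doublets,
ambient RNA), batch effects, a learned manifold embedding, zero-inflation
beyond Poisson sampling, and realistic motif grammar beyond single planted
consensus instances. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not robustness to every
artifact of real data.

## Validation problem sizes

The test suite and the acceptance script validate at these scales, chosen
to give stable statistics while keeping runs desk-sized: decay-length and
edge-sign recovery over 20 seeds at 2,000 cells; knockout direction over 20
seeds at 800 cells with 8 TFs and 40 genes; clonal-test calibration over
500 runs of 150 clones with 200 Monte-Carlo replicates each, and power at
200 fully concordant clones with 1,000 replicates; the base-network
arithmetic at the full 50 × 4,306 matrix.

## Known limitations

* The Poisson RP likelihood ignores overdispersion; with strongly
  overdispersed data the ISD scores remain rankable but their likelihood
  units are optimistic.
* ISD scores can be negative (deleting a noisy peak can improve the
  refitted model); they are not clipped, and the global quantile cut
  operates on the raw values.
* The perturbation-flow kernel is a heuristic embedding of gene-space
  shifts; only the *sign* and relative magnitude of $\Delta\mathrm{PS}$
  are interpreted, not its units.
* The z-based clonal p-value inherits normal-approximation error in the
  extreme tails; at 200 replicates the usable floor is about $10^{-3}$.
* k-means on centrality profiles is seeded and restarted but still a local
  optimizer; cluster labels are reproducible, cluster *identity* across
  datasets is not guaranteed.
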