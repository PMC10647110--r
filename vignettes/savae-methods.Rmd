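---
title: "Similarity-assisted variational autoencoders: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-assisted variational autoencoders: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep generative models give nonlinear dimension reduction with an
encoder/decoder pair: new samples can be mapped into the latent space and
latent points can be decoded back into data space. A plain variational
autoencoder (VAE), however, tends to produce latent spaces without clear
grouping structure, while neighbourhood-based methods such as UMAP produce
clear groups but have no encoder or decoder. This package trains a VAE whose
latent space is additionally regularized by the UMAP-style fuzzy
cross-entropy, so the fitted model keeps the generative structure *and* the
grouping power of similarity-based embeddings. A two-stage conditional
variant removes known covariate effects (batch, donor, technical fractions)
before similarities are computed, for single-cell RNA-seq style data.

## Model

**Generative part.** Each sample $x$ has a latent $z \in \mathbb{R}^J$ with
prior $N(0, I)$. The decoder maps $z$ (optionally concatenated with a
covariate code) to the parameters of the observation family: Bernoulli
probabilities for binarized data, a unit-variance Gaussian mean for
continuous data, or a negative-binomial (NB) mean for counts, with one free
dispersion $r_g > 0$ per feature. The variational posterior is
$q(z \mid x) = N(\mu_\phi(x), \mathrm{diag}\,\sigma^2_\phi(x))$; for count
likelihoods the encoder reads $\log(1 + x)$. Encoder and decoder are MLPs
with three fully connected layers and ReLU activations on the hidden ones.
The negative evidence lower bound
$-\mathbb{E}_q \log p(x \mid z) + \mathrm{KL}(q \,\|\, p)$
is estimated with a single reparametrized draw
$z = \mu + \sigma \odot \varepsilon$ and minimized with Adam
(learning rate $10^{-3}$).

**Similarity part.** On the encoder-input representation, a fuzzy similarity
graph is built the way UMAP builds one: exact $k$-nearest neighbours
(default $k = 30$), per-sample local connectivity distance $\rho_i$ (the
smallest positive neighbour distance) and bandwidth $\sigma_i$ solving
$\sum_j \exp(-\max(0, d_{ij} - \rho_i)/\sigma_i) = \log_2 k$ by bisection,
directed weights $w_{ij} = \exp(-\max(0, d_{ij}-\rho_i)/\sigma_i)$, and the
probabilistic t-conorm symmetrization
$\mu_{ij} = w_{ij} + w_{ji} - w_{ij} w_{ji}$. Low-dimensional similarity is
the rational curve $\nu(d) = 1/(1 + a d^{2b})$, with $(a, b)$ least-squares
fitted to the piecewise-exponential target determined by `min_dist`
(default 0) and `spread` (default 1).

**The combined objective.** For a pair of samples, the *expected*
low-dimensional similarity
$\tilde\nu_{ij} = \mathbb{E}_{q(z|x_i)}\mathbb{E}_{q(z'|x_j)}
  \,\nu(\lVert z - z' \rVert)$
makes the fuzzy cross-entropy
$-\sum_{i \ne j} \mu_{ij}\ln\tilde\nu_{ij} +
  (1-\mu_{ij})\ln(1-\tilde\nu_{ij})$
a function of the encoder parameters, so it can be added to the VAE loss
with weight $\lambda$ (default $10^3$). Both expectations use a single
reparametrized draw, and gradients flow through both draws.

**Stochastic estimation.** The double sum is estimated by negative
sampling. Each minibatch anchor draws one positive partner with probability
proportional to $\mu_{i\cdot}$; the sampling frequency absorbs the
$\mu_{ij}$ factor, so each visited pair contributes $-\ln\tilde\nu_{ij}$.
Every positive pair draws $M = 5$ negatives uniformly with replacement from
the augmented minibatch (anchors plus positives); negatives carry target
similarity 0 and contribute $-\ln(1-\tilde\nu)$, with their $(1-\mu)$
factor taken as 1 (exact under uniform draws up to the vanishing chance of
hitting a true edge). A draw that collides with its anchor is redrawn once
and then kept. The anchors are interleaved with their positives,
$\{x_i, x_i^1, x_i, x_i^2, \dots\}$, and this unpacked batch is what the
VAE term sees.

**Balancing the two losses.** Per outer step the trainer performs one Adam
update of the VAE loss on the unpacked batch and $I = 5$ updates of
$\lambda\times$ the regularizer on freshly resampled pairs. The regularizer
touches only encoder parameters; both objectives share one Adam instance,
so the relative gradient magnitudes (set by $\lambda$) determine how
strongly the similarity signal dominates the shared encoder moments. With
$\lambda = 0$ and no positives the procedure reduces exactly — bitwise,
under a fixed seed — to plain VAE training.

## The conditional variant

With covariates $s$ (one-hot blocks for categoricals, standardized values
for continuous ones) the decoder always receives $[z, g(s)]$, where $g$ is
a covariate sub-network: one fully connected layer with ReLU, batch
normalization and dropout (rate 0.1), width 128. By default the encoder is
*not* conditioned: $q(z \mid x)$ absorbs the covariate shift during
training because the decoder no longer needs the latent space to carry
covariate information. The fully conditional encoder $q(z \mid x, s)$ is
available as a flag, in which case corrected embeddings fix $s$ at a
reference value $s_0$ (first categorical level, zero for standardized
continuous covariates).

The two-stage procedure (`fit_sacvae()`) first trains a plain CVAE; its
covariate-adjusted embeddings define the similarity graph (Euclidean metric
on the latent means), which is then used to train a fresh CVAE with the
regularizer. Stage 2 cannot repair a failed stage 1 — if the stage-1
latent is still batch-structured, the graph inherits it — so the stage-1
budget should be large enough for the covariate sub-network to absorb the
batch variance. Both stages use the same seed stream (stage 2 derives its
seed as `seed + 1`).

## Numerical choices

- **Bisection for $\sigma_i$**: absolute tolerance $10^{-5}$, at most 64
  iterations, doubling upper bracket. Samples whose adjusted neighbour
  distances are all zero (duplicates; all neighbours equidistant at
  $\rho_i$) have a constant neighbour sum, so no root exists; they get
  $\sigma_i = 1$ and are flagged. The single-neighbour case with target
  $\log_2 1 = 0$ is the same degenerate path.
- **Curve fit**: Levenberg–Marquardt nonlinear least squares from
  $(a, b) = (1, 1)$ on a 300-point grid over $[0, 3\,\mathrm{spread}]$;
  on failure the published defaults $(1.577, 0.895)$ are used with a
  warning.
- **Clamping**: $\tilde\nu$ is clamped to $[10^{-6}, 1 - 10^{-6}]$ inside
  both logarithms; squared distances are floored at $10^{-8}$ in the
  attractive power term and the repulsive coefficient uses
  $d^2 + 10^{-3}$ in its denominator, the standard stabilizers for the
  $b < 1$ regime where raw gradients diverge as paired draws coincide.
- **Force clipping**: per-dimension pairwise forces are clipped at
  $|4|$, as in reference edge-wise fuzzy cross-entropy optimizers; without
  it occasional near-coincident draws dominate the shared Adam moments.
- **NB head**: decoder means are `softplus(o) + 1e-6` for positivity;
  dispersions are parameterized as `exp(log_r)` and learned per feature
  (a fixed-dispersion mode is retained).
- **Scale head**: the encoder emits log-variance; `scale = exp(output/2)`.
- **Initialization**: uniform fan-in for all layers; zero-initialized
  output heads exist only as a test fixture.
- **Determinism**: all training randomness flows through R's RNG from a
  single `seed`; the two-moons generator carries its own
  Mersenne–Twister stream so it reproduces the canonical scikit-learn
  construction bit-for-bit without touching the session RNG.

## Design choices where the design was open

- **Estimator weighting.** Sampling positives proportional to $\mu$ *and*
  multiplying the attractive term by $\mu_{ij}$ would weight edges by
  $\mu^2$; we follow the canonical negative-sampling scheme in which the
  sampling frequency carries the $\mu$ weight and each visit contributes
  an unweighted $-\ln\tilde\nu$. The package's estimator has expectation
  $\sum_i \sum_j (\mu_{ij}/S_i)(-\ln\tilde\nu_{ij})$ per anchor,
  $S_i = \sum_j \mu_{ij}$, which the property suite checks on small
  instances.
- **Exact neighbour search everywhere.** At the problem sizes this package
  targets (up to a few tens of thousands of samples) chunked brute-force
  Euclidean search is fast, exact, and removes an approximation layer;
  an approximate backend can be added behind `knn_search()` if needed.
- **Positives/negatives per anchor**: $P = 1$, $M = 5$ (the reference
  edge-sampling defaults); both configurable.
- **Inner updates resample pairs** each of the $I$ iterations — they are
  stochastic gradient steps on the same objective, so fresh samples are
  the natural choice. Only the regularizer (not the KL) is updated in
  inner steps.
- **$\lambda$ default $10^3$**; the selection rule "largest value that
  still decreases the VAE loss" can be emulated with a short probe over a
  grid, but the default is used throughout the tests.
- **DBSCAN noise points** share one distinct cluster label before ARI/NMI
  are computed; k-means uses the true class count with 10 seeded restarts.
- **NMI normalization**: arithmetic mean of the two entropies; identical
  trivial partitions score 1, a single cluster on one side only scores 0.
- **Negatives are not screened against the anchor's true edges**: under
  uniform draws from a minibatch the chance of hitting a genuine
  neighbour is negligible, and screening would bias the repulsive mass.
- **HVG recipe**: total-count normalization to the median, per-gene
  variance/mean dispersion, z-scored within 20 equal-frequency mean bins;
  constant genes rank last. Selection happens on the full matrix.

## What the synthetic generators emulate — and what they do not

`make_two_moons()` reproduces the canonical two-interleaving-half-circles
benchmark (default: 2000 points per class, noise 0.05, seed 42) exactly as
the standard Python generator produces it, so results are directly
comparable with the wider literature on this fixture.

`make_synth_counts()` draws NB counts with per-gene log-normal base means
(log-mean $\log 2$, log-sd 1), dispersion $r = 2$, uniform group and batch
assignments, and planted log-fold effects: each group perturbs a random
10% of genes by $\pm 1.5$; each batch beyond the first shifts a random 25%
of genes by $\pm 1$. In this regime PCA + k-means recovers groups when no
batch shift is present, and a planted batch shift separates batches within
every group (a genuinely confounded regime). What these generators do *not*
emulate: library-size variation, zero inflation beyond NB sampling,
doublets, gene–gene correlation beyond the group/batch structure, or
continuous trajectories. Passing tests on them demonstrates correct
mechanics and the claimed qualitative behaviours, not performance on real
tissue data.

## Problem sizes used in the checks

The end-to-end checks run the full two-moons protocol (4000 points,
200 epochs, batch 128, five seeds) and NB-count experiments with 5000
cells and 800 generated genes, screened to the top 400 highly variable
genes before fitting — the standard preprocessing step of the count
workflow, which also doubles the training epochs affordable at equal
cost. The count models use hidden width 128 and a 10-dimensional latent
(the default for real 1200-gene data is 512), batch size 128, 5 epochs
for the unconditional saVAE-vs-VAE comparison and a 40-epoch stage 1 +
8-epoch stage 2 for the covariate experiment. Stage 1 needs the larger
share of the budget: the similarity graph is only as good as the
covariate-adjusted embeddings it is computed from, and the CVAE latent
needs tens of epochs before its neighbourhoods are group-pure and
batch-mixed. These sizes keep every behavioural margin under test
(group recovery, batch removal, the saVAE-vs-VAE ordering) wide while
the whole suite stays single-CPU friendly.

## Known limitations

- The latent geometry preserves *topology*, not blob-ness: on two moons
  the latent classes separate perfectly as filaments (density-based
  clustering finds them exactly) but stay elongated and interlocked, so
  centroid-based k-means can cut across them. See the README's worked
  example for the measured numbers.
- Quality is bounded by the similarity graph; a poor metric or
  representation gives a poor regularizer (choose `transform` and the
  graph input deliberately).
- The two-stage conditional variant inherits stage-1 failures.
- Training is $O(n^2)$-free (negative sampling), but the exact k-NN build
  is $O(n^2)$ time at graph construction.
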