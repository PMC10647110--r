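# savae

Nonlinear dimension reduction with an encoder/decoder structure for
count and continuous data — bulk and single-cell transcriptomics in
particular. A variational autoencoder (VAE) is trained jointly with a
UMAP-style fuzzy cross-entropy regularizer computed on *expected*
low-dimensional similarities between variational posteriors, so the
fitted latent space shows the clear grouping structure of
neighbourhood-embedding methods while keeping a generative decoder and
an encoder for new samples. A two-stage conditional variant removes
known covariate effects (batch, donor, continuous technical fractions)
before similarities are computed.

## The model in brief

For samples $x_i$ with variational posteriors
$q(z \mid x_i) = N(\mu_\phi(x_i), \mathrm{diag}\,\sigma^2_\phi(x_i))$
and decoder family $p_\theta(x \mid z)$ (Bernoulli, unit-variance
Gaussian, or negative binomial with learned per-gene dispersion), the
training objective is

$$
-\mathbb{E}_{q}\log p_\theta(x\mid z) + \mathrm{KL}(q \,\|\, N(0,I))
\;-\; \lambda \sum_{i\neq j}\Big[\mu_{ij}\ln\tilde\nu_{ij}
 + (1-\mu_{ij})\ln(1-\tilde\nu_{ij})\Big],
$$

where $\mu_{ij}$ are UMAP fuzzy graph similarities computed on the
encoder-input representation ($k$-nearest neighbours, smooth local
scaling, t-conorm symmetrization) and
$\tilde\nu_{ij} = \mathbb{E}_{q(z|x_i)}\mathbb{E}_{q(z'|x_j)}
 \,[1 + a\lVert z-z'\rVert^{2b}]^{-1}$
is the expected low-dimensional similarity. The double sum is estimated
by negative sampling (positives drawn proportional to $\mu$, $M$
uniform negatives per pair) and the regularizer is updated $I$ times per
VAE update with weight $\lambda$ (defaults $\lambda = 10^3$, $I = 5$,
$k = 30$, `min_dist = 0`). With covariates, the decoder receives a
one-hot / standardized covariate encoding through a small sub-network;
the unconditionally trained encoder $q(z \mid x)$ then serves as the
covariate-adjusted embedding, and `fit_sacvae()` rebuilds the
similarity graph from those embeddings before the final regularized fit
(two stages).

## Worked example

Two interweaving half circles (2000 points per class, noise 0.05 — the
canonical construction, reproduced bit-for-bit):

```r
library(savae)

moons <- make_two_moons(n_per_class = 2000, noise = 0.05, seed = 42)
fit <- fit_savae(moons, latent_dim = 2, hidden_dim = 20,
                 likelihood = "gaussian", k = 30, min_dist = 0,
                 lambda = 1e3, update_ratio = 5, epochs = 200,
                 batch_size = 128, seed = 1)
glance(fit)
#> # A tibble: 1 × 8
#>   method     n latent_dim epochs recon    kl  umap  seed
#>   <chr>  <int>      <int>  <int> <dbl> <dbl> <dbl> <dbl>
#> 1 savae   4000          2    200  1.84  117.  57.0     1

evaluate_embedding(fit, k_true = 2, seed = 1)
#> # A tibble: 1 × 6
#>   method   eps min_samples   ari   nmi mean_score
#>   <chr>  <dbl>       <dbl> <dbl> <dbl>      <dbl>
#> 1 dbscan   0.9           5     1     1          1
```

The reconstruction error of the saVAE decoder is two orders of
magnitude below a plain VAE trained with the same budget (mean squared
error 0.0026 against 0.50 — the regularized latent space preserves the
information the decoder needs), and density-based clustering of the
latent space recovers the two classes exactly: the two moons map to two
clearly separated filaments that preserve their interweaving shape, so
the DBSCAN arm of the parameter search attains ARI = NMI = 1 while
plain k-means, which must cut the plane with a single line between two
elongated interlocked arcs, does not (its ARI is about 0.29).
`autoplot(fit)` shows the latent space; `plot_history(fit)` the loss
trajectories.

For counts, the same interface with an NB decoder:

```r
cnt <- make_synth_counts(n_cells = 5000, n_genes = 800, n_groups = 4,
                         seed = 100)
hv <- select_hvg(cnt, 400) # standard screening step
fit <- fit_savae(hv, latent_dim = 10, hidden_dim = 128,
                 likelihood = "nb", k = 30, epochs = 5,
                 batch_size = 128, seed = 1)
set.seed(1)
ari(kmeans(fit$latent, 4, nstart = 10)$cluster, cnt$labels)
#> [1] 1
```

and with a planted two-level batch shift, the two-stage conditional fit
removes the batch structure from the latent space
(`fit_sacvae(...)`; group ARI stays high while clustering against the
batch label drops to zero — see `vignette("savae-methods")` and the
test suite for the exact protocols).

A thin command-line front end over these functions is installed with
the package (`system.file("cli", "savae", package = "savae")`), with
subcommands `simulate`, `fit`, `evaluate` and `viz` operating on
Matrix Market / CSV / TSV files.

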