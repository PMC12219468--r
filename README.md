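# unidim

Quantifying which representational dimensions of neural networks are
**universal** — learned again and again by different networks — and which of
those are **shared with the brain**.

## The problem

Different vision networks trained on the same stimuli learn partly
overlapping representations. For every latent dimension *d* of a network
layer (a principal component of its spatially pooled activations), this
package computes two statistics:

```
Universality_d   = median( r_d,1 , … , r_d,m )   over m predictor networks
BrainSimilarity_d = mean ( r_d,1 , … , r_d,n )   over n subjects
```

where each `r` is the accuracy (Pearson correlation, averaged over five
outer cross-validation folds) with which a nested cross-validated ridge
regression predicts dimension *d* from another network's concatenated
pooled layers, or from one subject's voxel responses. The inner loop
selects the ridge penalty per target by leave-one-out cross-validation
among {0} and eight log-spaced values in [1e-3, 1e4].

Downstream, the package relates the two metrics by Spearman and partial
Spearman (controlling for PC rank) correlations, attaches a one-sided
image-label permutation test (labels shuffled per target network before
universality is recomputed; add-one corrected p), summarizes the trend in
quantile bins, and runs representational similarity analysis (RSA) in which
each network is reduced to the subspace of its top-10 or top-5 most
universal dimensions before its representational geometry is compared with
the subjects'.

Because the full-scale inputs (activations of model zoos, fMRI recordings)
are external, the package ships a latent-factor world generator that
emulates the statistical structure the analysis assumes: networks mixing
shared and idiosyncratic latents, subjects mixing (a subset of) the shared
latents — or, in the *null world*, latents disjoint from every network.
All claims are tested against this generator's planted ground truth. It is
intended for methodologists who want a tested, reusable reference
implementation of the universality/brain-similarity pipeline, applicable to
real activation matrices via the documented CSV/JSON container layout.

## Worked example

```r
library(unidim)

cfg <- run_config(world = world_config(), n_perm = 199, seed = 1)
res <- run_all(cfg, quiet = TRUE)

round(c(rho   = res$summary$rho,
        rho_p = res$summary$rho_partial,
        p     = res$summary$p_value), 3)
#>   rho rho_p     p
#> 0.543 0.521 0.005

tail(res$quantiles, 3)
#>    bin mean_universality mean_brain_similarity
#> 8    8        0.04079326            0.02914835
#> 9    9        0.06284652            0.03815472
#> 10  10        0.10694038            0.08141684

res$rsa$network1$test_similarity_full
#> [1] 0.946107
res$rsa$network1$test_similarity_reduced
#>        10         5
#> 0.9647884 0.9646570
```

What these numbers mean: across the 1,080 scored dimensions of six
simulated networks, dimensions that other networks can predict are also the
ones the four simulated subjects' voxels predict (Spearman ρ ≈ 0.54,
surviving control for PC rank at ρ ≈ 0.52), and the association beats all
199 label permutations (p = 1/200, the add-one floor). The quantile curve
rises steadily with universality; the 54 planted shared dimensions sit
above the last full bin (the equal-size rule drops the final partial
quantile) with universality ≈ 0.98 and brain similarity ≈ 0.98. Reducing
the selected layer to its ten (or five) most universal dimensions does not
reduce RSA test similarity — the universal subspace carries the network's
representational geometry.

A thin command-line front end is provided at `inst/scripts/unidim.R`
(`run-all`, `simulate`, `report` subcommands over the same functions).

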