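# pmnmm — penalized matrix normal mixture models

`pmnmm` clusters matrix-valued observations — grayscale images,
channel × time recordings, any data whose rows and columns both carry
meaning — with a finite mixture of matrix normal distributions.  Each
component has a `p × q` mean matrix `M_j` and a Kronecker-separable
covariance `V_j ⊗ U_j` (a `p × p` row factor and a `q × q` column factor),
so the density of an observation `X` is

    f(X | M, U, V) = (2π)^(-pq/2) |V|^(-p/2) |U|^(-q/2)
                     exp{ -1/2 tr( V⁻¹ (X−M)ᵀ U⁻¹ (X−M) ) }

Parameters are estimated by maximizing a penalized mixture log-likelihood
with three lasso terms,

    L_p(Θ) = Σ_i log Σ_j π_j f(X_i | Θ_j)
             − λ₁ Σ_j |M_j|₁ − λ₂ Σ_j |U_j⁻¹|₁ − λ₃ Σ_j |V_j⁻¹|₁ ,

via an EM algorithm whose M-step soft-thresholds the component means and
solves graphical-lasso subproblems for the row and column precision
matrices (an ADMM solver with verified KKT optimality ships with the
package).  The mean penalty zeroes non-discriminating pixels; the precision
penalties impose Gaussian-graphical sparsity on the conditional dependence
of rows and columns, which is what keeps the model estimable when `n` is
small relative to `pq`.  Stopping uses Aitken acceleration of the penalized
log-likelihood; fits are multi-started from seeded K-means initializations.

The package also provides k-fold cross-validated grid search over
`(G, λ₁, λ₂, λ₃)`, clustering metrics (accuracy under optimal label
matching, adjusted Rand index), estimation-error norms, two built-in
simulation scenarios (banded and AR(1) vec-level precision structures),
CSV/JSON input-output and a command-line interface.  See the methods
vignette (`vignettes/pmnmm-methods.Rmd`) for the algorithmic details and
design decisions.

## Worked example

```r
library(pmnmm)

# two-group benchmark: rectangle vs cross mean patterns on 20x20 matrices,
# banded (non-separable!) precision of vec(X)
spec <- scenario_spec(1, n = 100, seed = 42)
ds   <- sample_scenario(spec)

fit  <- fit_pmnmm(ds$samples, G = 2,
                  penalty_config(lambda1 = 5, lambda2 = 0.001, lambda3 = 0.01),
                  seed = 7)
fit
#> Penalized matrix normal mixture: G = 2 components, 20 x 20 matrices
#>   weights: 0.55, 0.45
#>   penalties: lambda1 = 5, lambda2 = 0.001, lambda3 = 0.01
#>   EM: 3 iterations, converged = TRUE, penalized loglik = -59433.2782

pred <- predict_labels(ds$samples, fit)
clustering_accuracy(ds$labels, pred)
#> [1] 1
adjusted_rand_index(ds$labels, pred)
#> [1] 1
sapply(fit$components, function(c) sum(c$M == 0))   # mean sparsity
#> [1] 113  69
```

The two groups are recovered exactly (accuracy and ARI both 1), and the
mean penalty has zeroed 113 and 69 of the 400 mean entries per component —
background pixels that carry no cluster signal.  Larger precision penalties
produce sparse precision factors as well: refitting with
`penalty_config(5, 1, 1)` zeroes 9–14 of the 190 off-diagonal entries of
each row-precision factor while accuracy stays 1.

Hyperparameter selection over the benchmark grids
(4-fold cross-validation):

```r
cv <- grid_search(ds$samples, G_values = 2,
                  lambda1_grid = c(20, 10, 5, 1, 0.5, 0.1),
                  lambda2_grid = c(1, 0.1, 0.01, 0.001),
                  lambda3_grid = c(1, 0.1, 0.01, 0.001),
                  K = 4, seed = 1)
cv$best
```

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/pmnmm.R simulate --scenario 1 --n 100 --seed 7 --out data/
Rscript inst/cli/pmnmm.R fit --data data/ --G 2 \
    --lambda1 5 --lambda2 0.001 --lambda3 0.01 --out model.json
Rscript inst/cli/pmnmm.R evaluate --data data/ --model model.json
```

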