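# coconet

Which tissue — or cell type — is the one through which a trait's genetic
associations act? `coconet` answers this by integrating two kinds of
evidence: gene-level effect measurements from a GWAS (standardized
per-SNP gene-level heritability estimates) and tissue-specific gene
co-expression networks from expression studies. If a tissue is relevant
to the trait, genes connected in that tissue's network should have
correlated effects on the trait; in an irrelevant tissue the network
should predict nothing.

## The model

For `m` genes, the effect vector `y` is modelled as multivariate normal
whose covariance is a function of the tissue's binary, symmetric,
zero-diagonal adjacency matrix `A`:

    y ~ MVN(1*mu, sigma0^2 I + sigma1^2 A)        (general: sum_k sigma_k^2 A^(k))

where `A^(k)`, the k-th matrix power with zeroed diagonal, counts k-paths
between genes, and `rho = sigma1^2 / (sigma0^2 + sigma1^2)` measures the
share of covariance explained by direct network connections. Parameters
are estimated by maximizing the **pairwise composite log-likelihood**

    l(theta) = sum_{i<j} log P(y_i, y_j | theta)

with Nelder–Mead. Grouping pairs by their covariance pattern reduces each
likelihood evaluation to a handful of closed-form terms, so the cost is
quadratic in `m` once (for grouping), then constant per evaluation:
thousands of genes fit in milliseconds. Candidate tissues are fitted one
at a time and **ranked by their maximized composite likelihood**; the
rank-1 tissue is the inferred trait-relevant tissue. An edge-subsampling
reproducibility score quantifies how stable each rank position is.

## Worked example

```r
library(coconet)
set.seed(7)

# five synthetic tissue networks (500 genes, 10-15 clusters each);
# the outcome is generated from tissue_2 at signal strength rho = 0.05
tissues <- replicate(5, generate_block_adjacency(500, 10:15), simplify = FALSE)
names(tissues) <- paste0("tissue_", 1:5)
y <- simulate_outcome(tissues[["tissue_2"]], rho = 0.05)

coconet(y, tissues[["tissue_2"]])
#> Composite-likelihood covariance regression network model (K = 1 )
#>   genes: 500   pairs: 124,750   edges: 11,289
#>   coefficients:
#>        mu sigma0_sq sigma1_sq
#>    0.0515    0.9496    0.0542
#>   rho = 0.05397   logLik = -347576.0243   BIC = 695187.2507

coconet_rank(y, tissues)
#> Tissue ranking by maximum composite likelihood (K = 1 )
#>    tissue       loglik delta_loglik         bic rank
#>  tissue_2 -347576.0243      19.0181 695187.2507    1
#>  tissue_3 -347594.7929       0.2494 695224.7880    2
#>  tissue_4 -347595.0401       0.0023 695225.2823    3
#>  tissue_5 -347595.0419       0.0004 695225.2860    4
#>  tissue_1 -347595.0423       0.0000 695225.2869    5
```

The generating tissue is recovered at rank 1 with a likelihood margin of
about 19 units over the runner-up, while the irrelevant tissues are
essentially tied (`delta_loglik` is the likelihood minus the worst
tissue's likelihood); the fitted `rho = 0.054` matches the generating
signal strength 0.05. Rank stability under 10% edge removal:

```r
coconet_reproducibility(y, tissues, seed = 7)$scores
#> rank1 rank2 rank3 rank4 rank5
#>   1.0   1.0   0.3   0.0   0.4
```

Rank 1 is reproduced in every subsample; the near-tied bottom ranks
churn, as they should.

Real inputs are prepared with `standardize_effects()` (per-SNP scaling +
standardization of gene-level heritability), `threshold_network()` (hard
thresholding of continuous edge scores with specificity masks),
`build_distance_matrix()` (scaled TSS distances as an optional extra
covariance component) and `align_genes()`; `read_adjacency()` /
`read_effects()` handle Matrix Market and TSV files. A command-line
interface mirrors the R functions:

```sh
./exec/coconet fixtures --out-dir demo --seed 1
./exec/coconet rank --effects demo/effects.tsv --adjacency-dir demo --out ranking.tsv --seed 1
./exec/coconet simulate --scenario I --rho 0.02 --seed 1 --out sim.tsv
```

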