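# daemkl

Multi-omics cancer subtyping by denoising-autoencoder multi-kernel
learning.

Molecular subtypes — patient subgroups with shared molecular profiles and
distinct prognosis — are rarely visible in a single omic layer. `daemkl`
integrates several layers (e.g. miRNA expression, mRNA expression,
gene-level DNA methylation) measured on the same samples into one fused
sample-similarity kernel and clusters it. It is aimed at computational
biologists who have a handful of preprocessed omic matrices and want
subtype calls, the relative weight each omic contributed, and an estimate
of how many subtypes the data supports.

## The method

For omics $m = 1, \dots, M$ with matrices $X_m$ (samples × features):

1. **Denoise and compress** each omic with a denoising autoencoder
   (masking corruption, tied weight-normalized encoder, proximal L1 that
   performs sparse feature selection): $Z_m = f_{\mathrm{enc}}(X_m)$.
2. **Learn a composite kernel per omic**: 55 adaptive-bandwidth Gaussian
   kernels on $Z_m$ (bandwidth grid $\sigma \in \{1,\dots,2\}$ by 0.25,
   neighbors $k \in \{10,\dots,30\}$ by 2), combined by alternating
   minimization over a row-stochastic similarity $S$, simplex kernel
   weights $w$, and an orthonormal low-rank factor $L$:
   $\min -\sum w_l K_l \odot S + \beta\lVert S\rVert_F^2 +
   \gamma\,\mathrm{tr}(L^\top(I-S)L) + \rho \sum w_l \log w_l$.
3. **Fuse** the composite similarities,
   $S_{\mathrm{final}} = \sum_m \beta_m S_m$, with simplex weights
   $\beta$ from an exactly solved quadratic program that minimizes
   graph-weighted distortion across the omics' shared kNN topology.
4. **Cluster** the rows of $S_{\mathrm{final}}$ with k-means; a
   spectral-rotation separation cost $\xi \ge n$ (equality at perfect
   indicator structure) ranks candidate cluster counts by how close each
   one comes to that ideal.

Ablation variants are built in: a sparse autoencoder (`sae-mkl`), a plain
autoencoder (`ae-mkl`), the pipeline without any autoencoder (`hmkl`),
and a pooled-kernel single-optimization baseline (`cimlr-joint`).
A synthetic four-subtype, three-omic benchmark generator with
complementary one-vs-rest signal placement makes every stage testable
without downloads, and `nmi()` scores partition recovery.

## Worked example

```r
library(daemkl)

cfg  <- sim_config(signal_ratio = 0.10, noise_variance = 4, seed = 42)
data <- generate_scenario1(cfg)
data
#> multiomics_dataset: 200 samples, 3 omics x 1000 features, 4 subtypes
#>   signal_ratio=0.100 noise_variance=4.0 mean_shift=1.65 fuzzy=0.00 seed=42

res <- run_pipeline(data$omics,
                    pipeline_config(method = "dae-mkl", k = 4, seed = 42))
res$fusion
#> fusion_result: 3 omics, beta = (0.3268, 0.3398, 0.3334)
res$assignment
#> subtype_assignment: k = 4, inertia = 0.202, sizes: 50/54/46/50

nmi(res$assignment$labels, data$true_labels)
#> [1] 0.8885126
```

The near-uniform `beta` says the three simulated omics contributed
equally to the fused kernel — as they should, since each one carries the
signature of exactly one subtype. The NMI of 0.89 against the known
labels means the four planted subtypes were recovered almost perfectly at
this noise level; the same pipeline without the autoencoder stage
(`method = "hmkl"`) scores 0.70 on this replicate, which is the denoising
stage's contribution. On real data you would start from TSV matrices
(`read_omic()`, `filter_and_impute()`, `log2p1()`, `mad_select()`,
`aggregate_cpg()`) and typically explore `k = "auto"`.

A thin command-line front end ships in `inst/scripts/daemkl`
(subcommands `simulate`, `reduce`, `preprocess`, `subtype`, `evaluate`,
`bench`).

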