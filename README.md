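# hmrfclust

Spatially aware Bayesian clustering of spatial proteomics single-cell data.

Spatial proteomics assays (imaging mass cytometry, MIBI, CODEX) measure
dozens of protein markers per cell while preserving each cell's position in
the tissue. Standard single-cell clustering ignores the positions, yet cell
populations are spatially organized: cells of some types aggregate with
their own kind (autonomous interactions), others preferentially neighbour
specific different types (nonautonomous interactions). `hmrfclust` exploits
this by modelling the latent population labels as a **hidden Markov random
field** on the cell neighbour graph: with labels
`x_1..x_N ∈ {1..K}` and a symmetric K×K affinity matrix β,

```
p(x | β) ∝ exp( Σ_{(u,v) ∈ edges} β[x_u, x_v] )
```

so a cell's assignment is informed jointly by its marker expression —
modelled as independent Normal emissions under conjugate Normal–Gamma
priors — and by the labels of its spatial neighbours. Three affinity
parameterizations are supported: a fixed smoothing prior (`0p`,
β_kk = 0.5), a single learned shared affinity (`1p`), and per-cluster
affinities with derived cross-cluster terms (`kp`,
β_kl = ((1−β_k) + (1−β_l))/2), learned by double Metropolis–Hastings,
which cancels the intractable Potts normalizing constant exactly. Labels are
sampled by a collapsed Gibbs sweep (emission parameters integrated out);
unsupervised runs are summarized by the partition maximizing the posterior
expected adjusted Rand index against the posterior similarity matrix.

Besides unsupervised clustering the package supports **guided clustering**
from a quaternary prior expression matrix (expected marker levels per
population, encoded as expression-percentile priors) and **anchor-based
label transfer**: gated cells from a disaggregated assay pin clusters to
signatures through their emission sufficient statistics without entering
the spatial graph. A complete simulation framework (random-geometric tissue
graphs, interaction regimes, overlap-calibrated Gaussian mixtures, a
synthetic labelled cytometry pool and semireal assembly) and evaluation
metrics (V-measure, Davies–Bouldin) are included as first-class, tested
code.

## Worked example

Simulate a spatially structured dataset and compare the spatial `kp` model
with a nonspatial Gaussian-mixture baseline on the same expression values:

```r
library(hmrfclust)

g <- synthetic_spatial_graph(n_cells = 500, mean_degree = 6, seed = 1)
d <- simulate_forward(g, K = 8, M = 10, regime = "biased", seed = 2)
d
#> simulated_dataset: 500 cells, 10 markers, K=8

fit <- run_mcmc(d$expression, d$graph, K = 8, variant = "kp", seed = 3)
fit
#> hmrf_trace: 500 iterations, 500 cells, K=8, variant=kp, mode=unsupervised

est <- mpear_point_estimate(fit)
v_measure(d$true_labels, est)
#> homogeneity 0.8232  completeness 0.7816  v_measure 0.8018

v_measure(d$true_labels, fit_gmm_baseline(d$expression, K = 8, seed = 4))
#> homogeneity 0.7508  completeness 0.7073  v_measure 0.7284
```

On this dataset the spatial model lifts the V-measure from 0.73 to 0.80 by
borrowing strength across neighbouring cells.

Real data enters through CSV readers: `read_expression_csv()` (cells ×
markers, with `cell_id`/`sample_id` columns), `read_locations_csv()` +
`build_neighbour_graph()` or `read_edge_list_csv()` for the graph,
`read_prior_matrix_csv()` and `read_anchors_csv()` for guidance, and
`arcsinh_transform()` for variance stabilization. A thin command-line
wrapper with `simulate` / `fit` / `evaluate` subcommands is installed at
`inst/cli/hmrfclust.R`.

See the vignette (`vignettes/hmrf-clustering-methods.Rmd`) for the model,
the sampler, the simulation framework, and the package's numerical choices
and limitations.

## License

MIT (see `LICENSE`).
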