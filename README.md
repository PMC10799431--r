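# velogcn

Cell-specific RNA velocity estimation for single-cell RNA-seq, in R.

RNA velocity infers the time derivative of each cell's spliced expression
state from the balance of unspliced (intronic) and spliced (mature) reads,
pointing every cell along its differentiation trajectory. Classical
estimators fit one set of splicing kinetics per gene for the whole
population, which breaks down for genes with lineage-specific or
time-dependent regulation. `velogcn` instead predicts transcription,
splicing and degradation rates **per cell and per gene** with a graph
convolutional network (GCN) over the cell k-nearest-neighbour graph, trained
by a self-supervised *continuity objective* that needs no labels: each
cell's extrapolated state must land on the observed expression of candidate
future neighbour cells. The package is aimed at single-cell analysts who
have spliced/unspliced count layers (from Velocyto, kallisto|bustools,
Alevin-Fry, ...) and want velocity fields, confidence scores and driver-gene
rankings.

## Model

With smoothed layers $u_i, s_i$ for cell $i$, the velocity is

$$\tilde v_i = \beta_i \odot u_i - \gamma_i \odot s_i,$$

where $(\beta_i, \gamma_i)$ come from a two-layer GCN (width 64, ReLU,
softplus output head) propagating over
$\tilde D^{-1/2}(A + I)\tilde D^{-1/2}$. Training minimizes

$$w_f\,\mathcal L_+ + w_b\,\mathcal L_- + w_p\,\mathcal L_{\text{Pearson}},
\qquad (w_f, w_b, w_p) = (1, 1, 18),$$

where $\mathcal L_\pm$ are mean squared gaps between $s_i \pm \tilde v_i$
and the probability-weighted expression of candidate target (source)
neighbours — uniform over the candidates whose displacement has positive
cosine with $\pm\tilde v_i$ — and $\mathcal L_{\text{Pearson}}$ rewards
per-gene correlation of velocity with unspliced and against spliced
expression, fixing the sign that the extrapolation terms leave symmetric.
Optimization: Adam (AMSGrad), learning rate 0.001 decayed by 0.97 per epoch,
full-size batches, 100 epochs; forward pass, backpropagation and optimizer
are implemented in plain R/Matrix code. The package also ships the splicing
ODE simulator (constant, time-dependent and two-regime kinetics), the
consistency / continuity / correlation / direction metrics, velocity-graph
and embedding-projection utilities, and pseudotime-correlation driver
ranking. See the methods vignette (`vignettes/velocity-model.Rmd`) for the
full account.

## Worked example

Simulate the 500-cell x 30-gene population (3 genes with degradation rates
increasing over time), preprocess, train, and evaluate:

```r
library(velogcn)
vs <- simulatePopulation(n_cells = 500, n_genes = 30, n_reversed = 3, seed = 1)
vs <- preprocess(vs, preprocessConfig(n_top_genes = 30, n_pcs = 30,
                                      k_neighbors = 30,
                                      normalize_target = "none"))
fit <- trainVelocityModel(vs, seed = 1)
tail(fit$log[, c("epoch", "loss_forward", "loss_backward",
                 "loss_pearson", "total")], 3)
#>     epoch loss_forward loss_backward loss_pearson     total
#> 98     98     1.175043      1.219069    -1.028310 -16.11547
#> 99     99     1.167647      1.213499    -1.026328 -16.09276
#> 100   100     1.178539      1.225354    -1.043222 -16.37410
```

Both extrapolation losses settle near 1.2 (squared expression units) and
the Pearson term approaches its ideal -2 bound, meaning velocities
correlate with unspliced and anti-correlate with spliced expression.

```r
vs <- estimateVelocity(vs, fit)          # adds velocity + rate assays
summary(overallConsistency(velocity(vs), neighborGraph(vs)))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.7884  0.9318  0.9863  0.9632  0.9976  0.9997
```

Neighbouring cells receive near-parallel velocities (median cosine 0.99).
Binning cells by the simulation's true pseudotime into five ordered
pseudo-cell-types and scoring the annotated bin1→bin2→...→bin5 transitions:

```r
ct <- cut(pseudotime(vs), 5, labels = paste0("bin", 1:5))
SummarizedExperiment::colData(vs)$cell_type <- as.character(ct)
pairs <- lapply(1:4, function(i) c(paste0("bin", i), paste0("bin", i + 1)))
ds <- directionScore(vs, velocity(vs), neighborGraph(vs), pairs)
round(c(direction_score = ds$global,
        frac_positive = mean(ds$per_cell > 0, na.rm = TRUE)), 3)
#> direction_score   frac_positive
#>           0.581           1.000
```

Every boundary cell's velocity points towards the later pseudotime bin.
Driver genes are the ones whose expression climbs with pseudotime:

```r
rankDriverGenes(vs, top_n = 3)
#>   branch    gene correlation rank
#> 1    all gene_16   0.9814067    1
#> 2    all gene_11   0.9728916    2
#> 3    all gene_14   0.9727024    3
```

A command-line pipeline wrapping the same steps (subcommands `simulate`,
`preprocess`, `train`, `run`, ...) lives at `inst/cli/velogcn.R`.

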