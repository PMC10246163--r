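# chromafuse

Generative multimodal fusion for paired imaging-derived modalities, with
an intuitive chromatic view of what each modality contributes.

Neuroimaging studies routinely acquire several modalities per subject —
gray-matter volume maps, fractional anisotropy maps, spatial ICA maps,
functional network connectivity matrices — and psychiatric conditions such
as schizophrenia express themselves heterogeneously across them. Given a
*pair* of modalities, chromafuse learns, fully unsupervised:

* a **private** latent subspace per modality (information exclusive to it),
* a **shared** subspace (information the modalities covary on), fused from
  both modalities by a product of experts,

using a disentangled multimodal variational autoencoder (DMVAE). Subjects
are then clustered in the concatenated latent space
`[pr1 | sh | pr2]` with K-Means++ into **meta-chromatic patterns (MCPs)**,
colored by how irregular each subspace is relative to the variational
prior: red = private space of modality one, green = shared, blue = private
space of modality two. An MCP that is, say, green-dominated groups
subjects whose two modalities *jointly* deviate from the norm.

## The model in brief

Each modality is encoded into an axis-aligned Gaussian posterior split
into private and shared blocks. The two shared posteriors are fused in
closed form (precisions add, means are precision-weighted):

```
1/σ²_sh = 1/σ²_sh1 + 1/σ²_sh2,   μ_sh = σ²_sh (μ_sh1/σ²_sh1 + μ_sh2/σ²_sh2)
```

Training minimizes an 11-term objective: 5 KL divergences (pr1, sh1, pr2,
sh2 and the fused posterior, each against N(0, I)) plus 6 reconstruction
terms — each modality decoded from its own shared block, the fused block,
and the *other* modality's shared block (cross-generation). The package
also provides:

* a stratified 10-fold protocol with best-validation checkpointing,
  Hungarian matching of clusters across folds, per-MCP robustness, %SZ and
  %F statistics, Fisher/Holm enrichment tests and a site-effect check;
* cross-fold matching of shared latent dimensions (robust if the mean
  absolute matched correlation exceeds 0.7), point-biserial diagnosis
  correlations, and decoded interpolations along a chosen dimension;
* cross-modal reconstruction evaluation against prior / normal baselines;
* a synthetic-cohort generator with known ground-truth latent factors and
  plantable diagnosis-linked shifts, used for all validation.

Everything downstream of training uses posterior means, never samples, so
analyses are bitwise reproducible.

## Worked example

Generate a synthetic multi-site cohort, plant a 3-sd patient shift in the
first modality's private factors, train one fold, and inspect the MCPs:

```r
library(chromafuse)

sim    <- generate_cohort(synthetic_config(n_subjects = 200, d_pr1 = 3,
                                           d_sh = 6, d_pr2 = 3,
                                           noise_sd = 0.3, seed = 42))
cohort <- plant_subgroup(sim$cohort, "pr1", shift = 3)
plan   <- make_fold_plan(cohort$metadata, n_folds = 5, seed = 1)

feats <- chromafuse:::prepare_fold_features(cohort, plan$folds[[1]],
                                            list(mean_scope_a = "dataset"))
fit <- train_fold(feats$a, feats$b, split = plan$folds[[1]],
                  config = training_config(epochs = 30, lr = 5e-3, seed = 1),
                  d_pr1 = 4, d_sh = 8, d_pr2 = 4,
                  hidden_a = 24, hidden_b = 24)
glance(fit)
#> # A tibble: 1 × 6
#>   epochs best_epoch best_val n_params n_train n_val
#>    <int>      <int>    <dbl>    <int>   <int> <int>
#> 1     30         26     384.    29165     144    16

emb  <- embed_subjects(fit$model, feats$a, feats$b)
cl   <- cluster_kmeanspp(emb, k = 3, seed = 1)
cols <- color_mcps(cl)
cols$pct_sz <- sapply(cols$mcp, function(c0)
  round(100 * mean(cohort$metadata$diagnosis[cl$labels == c0] == "SZ")))
cols
#> # A tibble: 3 × 9
#>     mcp n_members norm_pr1 norm_sh norm_pr2   red green  blue pct_sz
#>   <int>     <int>    <dbl>   <dbl>    <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1     0        53     4.05   0.665    0.351 1     1     1         96
#> 2     1        93     3.53   0.239    0.204 0.870 0.360 0.581      2
#> 3     2        54     3.06   0.638    0.324 0.754 0.959 0.925     85
```

Reading the table: `norm_*` are the L2 norms of each MCP center in the
three subspaces (its distance from the prior mean), and `red`/`green`/
`blue` are those norms divided by the per-subspace maximum over MCPs. MCPs
0 and 2 are patient-enriched (96% and 85% patients — well above the 70%
enrichment threshold) and carry the largest private-A irregularity, which
is exactly the planted effect; MCP 1 is control-dominated. The full
protocol — 10 folds, cluster matching, robustness/enrichment tables,
shared-dimension report, cross-reconstruction table — runs from a single
configuration with `run_pipeline(pipeline_config(...))`, which writes six
CSV artifacts plus a JSON manifest; `rerun_pipeline(<dir>)` reproduces
them byte-for-byte. A thin command-line wrapper for shell use lives at
`inst/cli/chromafuse` (`chromafuse run --config cfg.yaml --out out/`).

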