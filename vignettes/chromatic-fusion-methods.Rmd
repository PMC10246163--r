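---
title: "Chromatic fusion: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatic fusion: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

chromafuse analyzes a *pair* of imaging-derived modalities per subject —
typically a 3-D volumetric map (voxel-based morphometry, fractional
anisotropy, or multi-channel spatial ICA maps) together with a square
functional-connectivity matrix — and asks how the two modalities covary,
which information is exclusive to each, and how those three kinds of
information relate to a diagnosis. This vignette documents the model, the
analysis protocol, the synthetic validation cohorts, and the numerical and
design choices a maintainer should know about.

## The disentangled multimodal VAE

Each modality $m_j$ of subject $i$ is encoded by its own network into an
axis-aligned Gaussian posterior that is *partitioned* into a private block
and a shared block:

$$q_1(\mathrm{pr}_1, \mathrm{sh}_1 \mid m_1), \qquad
  q_2(\mathrm{pr}_2, \mathrm{sh}_2 \mid m_2).$$

The two shared blocks are fused by a product of experts (PoE). For diagonal
Gaussians the product is available in closed form — precisions add and the
mean is the precision-weighted average:

$$\frac{1}{\sigma^2_{\mathrm{sh}}} = \frac{1}{\sigma^2_{\mathrm{sh}_1}}
  + \frac{1}{\sigma^2_{\mathrm{sh}_2}}, \qquad
  \mu_{\mathrm{sh}} = \sigma^2_{\mathrm{sh}}\left(
  \frac{\mu_{\mathrm{sh}_1}}{\sigma^2_{\mathrm{sh}_1}} +
  \frac{\mu_{\mathrm{sh}_2}}{\sigma^2_{\mathrm{sh}_2}}\right).$$

`poe_combine()` implements exactly this and is tested against a normalized
numeric-grid product of the two densities.

The training objective (`dmvae_loss()`) has exactly **5 KL terms** — the
private and shared blocks of both encoders plus the PoE posterior, each
against the standard-normal prior — and **6 reconstruction terms**: each
modality decoded from its own encoded private block together with (i) its
own shared block, (ii) the PoE-fused shared block, and (iii) the *other*
modality's shared block (the cross-generation terms). The reconstruction
likelihood is a unit-variance Gaussian, so each reconstruction term is half
the summed squared error on the modeled features, averaged over the batch;
the additive $\tfrac{D}{2}\log 2\pi$ constant is dropped, which shifts
absolute loss values but no optimum. Modality weights $\lambda_1,
\lambda_2$ (default 1) scale the reconstruction sums.

Two subtleties worth recording:

* **Cross-term latent source.** For the two cross-generation *training*
  terms the modality's own *encoded* private block accompanies the other
  modality's shared block. At *inference* time (`cross_reconstruct()`,
  `evaluate_cross_reconstruction()`), the missing modality's private block
  is set to the prior mean (zeros). The first is the right training signal
  (the private code is available and should not be unlearned); the second
  is the honest imputation setting where the private code does not exist.
* **The PoE KL at the prior.** If both encoders emit exactly the prior
  $N(0, 1)$, the fused posterior is $N(0, \tfrac12)$ and its KL to the
  prior is $\tfrac12(\tfrac12 - \log\tfrac12 - 1) \approx 0.0966$ per
  shared dimension. The objective's floor is therefore not 0; tests assert
  the closed form rather than a naive zero.

### Architecture and training

No deep-learning framework is assumed: encoders and decoders are dense
(`tanh`) stacks with analytic reverse-mode gradients, verified against
central finite differences to ~1e-10 relative error. Volumes enter as
masked, flattened voxel vectors; connectivity matrices as their strict
lower triangle (`vectorize_connectivity()`). All sizes are configurable
(`dmvae_model()`), down to one-dimensional linear toys that make exact
oracle tests possible.

Defaults follow the reference protocol: 16 latent dimensions per private
space, 32 shared, 300 epochs with an Adam-family optimizer (labelled
AdamP) at learning rate 1e-5. Reparameterized sampling is used during
training only; every evaluation and all downstream analysis use posterior
*means*, making evaluations bitwise reproducible. `train_fold()` evaluates
the objective on a held-out validation split after each epoch and returns
the parameter snapshot of the minimum-validation epoch. An optional cosine
learning-rate schedule (`training_config(lr_schedule = "cosine")`) anneals
the step size to zero; the late-training annealing is what lets latent
axes settle, which measurably stabilizes shared-dimension matching across
folds. The log-variance heads are clamped to $[-15, 15]$ for numerical
safety; the clamp never binds in sane runs.

## Meta-chromatic patterns

After training, each subject is the concatenation of posterior means
$[\mathrm{pr}_1 \mid \mathrm{sh} \mid \mathrm{pr}_2]$ (64-dimensional under
defaults), where the shared block is the PoE fusion of both modalities
(`embed_subjects()`). Subjects are clustered with K-Means++
(`cluster_kmeanspp()`, 50 restarts, best inertia kept; Lloyd iterations
delegated to `stats::kmeans`). The number of clusters comes from the elbow
criterion (`select_k_elbow()`): the $k$ maximizing the second difference
of the within-cluster sum-of-squares curve, ties to the smaller $k$.

Each cluster — a *meta-chromatic pattern* (MCP) — is colored by
irregularity: the L2 norm of its center in each subspace (distance from
the prior mean, zero), divided by the maximum such norm over MCPs. Red is
private-A, green shared, blue private-B; the channel of the most irregular
MCP in a subspace is exactly 1. Subjects are colored by a probabilistic
assignment with weights proportional to (distance to each center)$^{-4}$,
normalized to one, times the MCP colors. Two degenerate cases are pinned
by design: a subject coincident with a center takes that center's color
exactly (the limit of the weight formula; ties split equally), and a
subspace in which *every* center has norm 0 gets channel 0 rather than
0/0. Clustering never sees diagnosis, sex or site — the analysis is fully
unsupervised; labels enter only afterwards, in the reporting.

## Robustness protocol

`make_fold_plan()` builds 10 stratified folds (diagnosis-stratified;
every fold's class counts within one subject of balance — subjects are
dealt around the folds with the rotation continuing across strata so the
total fold sizes are balanced too). Each fold trains its own model on the
remaining folds minus a stratified 10% validation subset, then embeds and
clusters the whole cohort. Fold 0 is the reference: every other fold's
clusters are matched to it by maximizing total overlap with the Hungarian
algorithm (`match_clusters()`; an O(n³) potential-based solver written for
this package and tested against exhaustive permutation search).

Overlap between two clusters is the **Jaccard percentage**
$100\,|A \cap B| / |A \cup B|$. The source protocol says "percentage of
subjects assigned to both clusters" without fixing a denominator; Jaccard
is chosen because it is symmetric and bounded, and the choice is pinned
here. When a fold has fewer clusters than the reference, unmatched
reference clusters score 0% for that fold.

Per reference MCP, `mcp_statistics()` reports the robustness (mean matched
overlap across folds) and the mean ± sd of the percentage of patients
(%SZ) and female subjects (%F) among matched members; MCPs above 70% mean
%SZ are flagged enriched. Pairwise differences in patient proportions are
tested with two-sided Fisher's exact tests, Holm-corrected across all MCP
pairs (`enrichment_significance()`) — an explicit design choice: exact at
small cluster sizes and conservative under the family-wise language of the
protocol. The same machinery applies to sex. `site_effect_check()`
computes, per MCP and site, the median over folds of the patient
percentage and reports the standard deviation across sites, flagging MCPs
at ≥ 5 percentage points. `heterogeneity_overlap()` quantifies how
distinct the patient sets captured by different enriched MCPs are (row
MCP's patients not captured by the column MCP, as a fraction of the row
MCP's patients, averaged over folds; diagonals are each MCP's unique share
of the pooled patients).

## Shared latent dimensions

Nothing guarantees that two training folds place the same shared factor in
the same latent dimension, or with the same sign. `match_shared_dims()`
correlates every reference-fold shared dimension with every dimension of
each other fold over the same subjects, solves the absolute-correlation
assignment problem per fold, records the matched sign, and flags
dimensions whose mean absolute matched correlation exceeds **0.7** as
robust. Matching operates on *subject scores* (not decoder weights) — an
explicit choice where the source protocol is silent. Constant dimensions
are excluded with a warning. `shared_dim_diagnosis()` adds the
point-biserial correlation with diagnosis (positive = higher in patients),
with the reference fold carrying the headline value and per-fold,
sign-aligned values alongside. `interpolate_dimension()` decodes a linear
traversal of one shared dimension with all other latents at the prior mean
(zero) — a deliberate choice over cohort means so the rendered panels are a
pure function of the chosen dimension; default endpoints are the 5th/95th
percentiles of the cohort's scores on that dimension.

## Cross-reconstruction evaluation

`evaluate_cross_reconstruction()` compares, on each fold's held-out test
subjects and per direction, three masked mean-squared errors: **prior**
(both latent blocks at zero; the lower bound), **normal** (the subject's
own encoded private and shared means; the upper bound), and **cross**
(zero private block plus the shared mean encoded from the other modality).
MSE is computed over modeled features per subject, then averaged, then
aggregated mean ± sd across folds. On standardized features the prior
column sits near 1.0 by construction — a useful sanity anchor.

## Preprocessing

For volumes: a single group mask from the voxelwise group-mean volume —
either rescale the group mean to [0, 1] and drop voxels below 0.15
(gray-matter / anisotropy maps) or drop voxels with absolute group mean
below 0.15 (signed ICA maps). The rescaling uses the group-mean volume's
min/max so the mask is subject-independent; the mask is treated as a
geometry choice and computed on all subjects, while the dataset-mean
removal and the per-feature z-scoring use *training-split statistics
only* (validation and test data are standardized with the training
moments). Spatial ICA maps have each subject's own scalar mean removed
instead of the dataset mean. Zero-variance features are dropped with a
warning. `resample_volume()` brings differently-sampled volumes onto a
common grid by trilinear interpolation, preserving the physical extent.

## The synthetic cohort generator

Real cohorts of this kind are rarely redistributable, so the package
ships a generator whose cohorts have *known* ground truth
(`generate_cohort()`): per-subject standard-normal private-A, shared and
private-B factors; modality A rendered as smooth Gaussian-blob spatial
basis maps (so decoded patterns look like blobs, as decoded brain maps
do), modality B as symmetric rank-one connectivity patterns; i.i.d.
Gaussian noise on top (symmetrized for B). Demographics mirror a
multi-site schizophrenia cohort: 278 subjects, 49.28% patients, 25.54%
female, 7 uniformly assigned sites with *no* injected site effect — the
site-effect check must therefore report dispersion near zero.
`plant_subgroup()` shifts the patients' mean in a chosen subspace (and
optionally chosen dimensions) and re-mixes through the stored bases and
noise, so the only difference is the planted effect; `ground_truth()` and
`cohort_signal()` expose the factors and the noiseless signal for oracle
tests.

Basis amplitudes decay geometrically across the factors of each subspace
(`mode_decay = 0.8`), emulating the dominant-mode variance spectrum of
imaging-derived components. This is not cosmetic: with exactly
exchangeable equal-amplitude shared factors the shared subspace is
identified only up to rotation, and *no* method can match individual
latent dimensions across independently trained folds — cross-fold
dimension matching presupposes a distinguishable spectrum, which real
components have. Setting `mode_decay = 1` restores the exchangeable case.

What the generator does **not** emulate: MRI physics and artifacts,
scanner/site batch effects, registration error, spatial autocorrelation of
noise, longitudinal structure. Passing the simulation studies therefore
shows the machinery is correct and the protocol recovers planted truth
under fair conditions — not that any particular real dataset will yield
robust MCPs.

## Study sizes used by the test-suite

The shipped validation studies are sized for a desk-scale, single-CPU run:
true latents 3/6/3 mixed into 8×8×8 volumes and 10×10 matrices with
noise sd 0.3; model dims 4/8/4 with 24 hidden units; learning rate 5e-3
(cosine-annealed for the longer runs), batch 32. Training sanity uses
n = 200 and 30 epochs; subgroup recovery plants a 3 sd private-A shift at
n = 300 (5 reruns, 4 required); shared-dimension recovery plants a 2 sd
shift on one shared factor at n = 300 with 3 folds × 100 epochs (5
reruns, 4 required); cross-reconstruction uses n = 150, 3 folds × 60
epochs, contrasting strong shared coupling against none; the end-to-end
reproducibility check runs n = 120, 3 folds × 20 epochs twice from the
saved manifest and compares artifacts byte-for-byte.

## Known limitations

* Dense encoders flatten volumes, ignoring 3-D locality; at full brain
  resolution a convolutional stack would be preferable. The module
  boundary (`encode()` / `decode()` / `dmvae_loss()`) is
  architecture-agnostic, so swapping stacks does not touch the protocol.
* K-Means++ with 50 restarts is not a global optimizer; seeds are recorded
  and the elbow curve is returned for inspection rather than trusted
  blindly.
* The enrichment tests condition on the clustering having been estimated
  from the same data (no selective-inference correction), matching the
  source protocol; p-values should be read as descriptive.
* Cross-reconstruction quality is bounded by the shared information
  actually present; with none, cross and prior coincide by design.
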