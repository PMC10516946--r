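# surfgradcam

Interpretable multi-view grading of alveolar bone defects on 3D surface
meshes, in R.

## What this is for

In cleft lip and palate (CLP) care, the bony defect of the maxillary
alveolar ridge is graded on a 0–3 severity index before secondary alveolar
bone grafting (0 = buccal depression with palatal support, 1 = unilateral
complete cleft, 2 = projected premaxilla with some palatal continuity,
3 = projected premaxilla with little or no palatal continuity). The grade
is read off a maxillary surface mesh segmented from CBCT. This package
implements an automatic grader for such meshes **and** the explanation
method that makes it auditable: every prediction can be rendered as a
per-vertex heatmap showing which parts of the bone drove the decision.

The pipeline is the *fly-by* multi-view approach:

* cameras on an icosphere render the pose-normalized mesh into 2D
  snapshots (surface normals + depth), each with a per-pixel **face-id
  buffer** recording which triangle produced every pixel;
* a small CNN encodes each view; its final conv maps `A^k` are retained;
* a gated **attention layer** turns per-view feature vectors into convex
  weights `a_v` and one shape descriptor `z = Σ_v a_v p_v`;
* a linear head gives 4 severity logits.

The explanation is **surface Grad-CAM**: for a target grade `c`, channel
weights are the spatial means of `∂logit_c/∂A^k` (the gradient flows
through the attention weighting), each view's class activation map is
`ReLU(Σ_k α_k^c A^k)`, and the per-view maps are **max-pooled** through
the face-id buffers onto the mesh — face value = max over all pixels in
all views that show the face, vertex value = max over incident faces,
never-visible vertices = exactly 0.

Patient meshes are not distributable, so the package ships a parametric
generator of labeled synthetic "cleft arch" meshes reproducing the four
morphologies (with ground-truth defect-region masks), which makes the
whole pipeline trainable and testable end to end.

## Worked example

```r
library(surfgradcam)

# 1. synthetic labeled dataset: 20 arches per grade
man  <- generate_dataset(rep(20L, 4), "arches", seed = 1)
vs   <- icosphere_cameras(0, radius = 3)      # 12 views
data <- render_dataset(man, vs, resolution = 64)

# 2. train (stratified 70/10/20 split, fold 1)
fa    <- split_dataset(data$labels, seed = 1)
model <- train_mvcnn(data, mvcnn_config(epochs = 40, seed = 1),
                     train_idx = fa$folds[[1]]$train,
                     val_idx   = fa$folds[[1]]$val)

# 3. predict a held-out mesh (a grade-0 specimen)
mesh <- read_mesh(file.path("arches", man$mesh_path[fa$folds[[1]]$test[1]]))
predict(model, mesh, vs)
#> $class
#> [1] 0
#>
#> $probs
#> [1] 0.6742654601 0.2366746262 0.0885037483 0.0005561654
#>
#> $logits
#> [1]  4.434763  3.387825  2.404184 -2.665551
#>
#> $attention
#>  [1] 0.1894145583 0.0789005638 0.0128962270 0.0252041764 0.0007808679
#>  [6] 0.0005700244 0.0012543664 0.0003829247 0.2460715352 0.2475141535
#> [11] 0.1197598380 0.0772507643

# 4. explain all four grades and write the heatmap mesh
out <- explain(mesh, model, target_classes = 0:3, viewset = vs)
names(out$vertex_scalars)
#> [1] "surfgradcam_class0" "surfgradcam_class1" "surfgradcam_class2"
#> [4] "surfgradcam_class3"
write_mesh("arch_heatmap.vtk", out)   # open in ParaView/Slicer, color by array
```

This 40-epoch demo model already grades the held-out depression specimen
correctly (grade 0 at probability 0.67; the full-length training used by
the evaluation suite is sharper). `probs` is the softmax severity
distribution, `attention` the convex per-view weights — here concentrated
on three of the twelve views — and each `surfgradcam_class*`
array a \[0, 1\]-normalized vertex heatmap of the evidence for that grade
(blue-to-red in a viewer).

A command-line wrapper with the same verbs
(`generate | train | predict | explain | evaluate`) is installed at
`inst/cli/surfgradcam`.

## Evaluation

`split_dataset()` + `cross_validate()` implement the full protocol:
stratified five-fold cross-validation (70% train / 10% validation / 20%
test per fold), per-class precision, recall, F1 and one-vs-rest AUC
(midrank Mann–Whitney), support-weighted totals, accuracy, row-normalized
confusion matrix and within-±1-grade agreement.

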