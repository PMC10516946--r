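---
title: "Multi-view severity grading of alveolar bone defects with surface Grad-CAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view severity grading of alveolar bone defects with surface Grad-CAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In cleft lip and palate (CLP) care, the alveolar bone defect — the bony gap
in the maxillary alveolar ridge at the cleft site — is graded on an ordinal
severity index from 0 to 3 before secondary alveolar bone grafting:

| grade | morphology |
|---|---|
| 0 | bone depression in the buccal aspect, palate supported |
| 1 | complete (full-thickness) cleft on at least one side |
| 2 | projected premaxilla, bilateral defect, some palatal bone continuity |
| 3 | projected premaxilla, large defect, small or no palatal continuity |

Grading is done by inspecting a 3D surface model of the maxilla segmented
from CBCT. This package automates the grading with a multi-view
convolutional classifier and, crucially, *explains* each decision by
painting a per-vertex importance heatmap onto the mesh (surface Grad-CAM),
so a clinician can verify that the model is looking at the defect and not
at a confounder.

## The pipeline

1. **Pose normalization** (`normalize_pose()`): centroid to the origin,
   maximum vertex radius scaled to 1. No rotational alignment is applied:
   the view sphere samples orientations densely enough that the classifier
   does not depend on a canonical pose, and clinical orientation (Frankfort
   plane) needs volumetric context that a surface mesh does not carry.
2. **Fly-by rendering** (`icosphere_cameras()`, `render_all()`): cameras at
   the vertices of a subdivided icosahedron look at the origin. Each view
   is rasterized into 4 channels — camera-space surface normal (x, y, z)
   and frustum-normalized depth — plus a per-pixel *face-id buffer*
   recording which triangle produced each pixel. The face-id buffer is the
   exact inverse mapping that later carries pixel importance back onto the
   surface.
3. **Per-view encoding** (`encode_view()`): a small conv stack; the
   post-ReLU feature maps of its final convolution are the Grad-CAM feature
   maps, and their spatial global average is the view descriptor.
4. **Attention aggregation** (`attention_aggregate()`): a gated scorer
   (`tanh` x `sigmoid`, one scalar per view) softmax-normalized into convex
   weights; the shape descriptor is the weighted sum of view descriptors.
   This is the standard gated attention-pooling formulation from
   multiple-instance learning; it makes the view weighting itself
   inspectable.
5. **Severity head** (`classify()`): linear map to 4 logits, softmax.
6. **Surface Grad-CAM** (`explain()`): for a target grade, the pre-softmax
   logit is backpropagated to every view's final conv maps *through the
   attention weighting*; channel weights are the spatial means of these
   gradients; each view's CAM is the ReLU of the weighted channel sum,
   bilinearly upsampled to render resolution; face values are the max over
   all pixels in all views pointing at the face, and vertex values the max
   over incident faces. Vertices never seen by any camera are exactly 0.

## Parameters that matter

* **View count / radius / field of view.** Default 12 views (icosphere
  level 0) at radius 3 (model units; the mesh has unit radius), fov 43°, so
  the specimen fills ~90% of the frame. 12 views keep a CPU training run in
  minutes; level 1 (42 views) is one config change.
* **Render resolution.** Default 64 px for training speed; 128 or 224 px
  work with the same code and make heatmaps crisper.
* **Backbone.** Default conv channels (8, 16, 32) with strides (2, 2, 1)
  and a final 32-channel stride-1 block, so the final feature maps are a
  quarter of the render resolution (16x16 at 64 px). The final maps are
  kept fine because they bound the spatial resolution of the class
  activation maps: an 8x8 CAM cell covers a region wider than a narrow
  cleft gap. Classification accuracy is insensitive to this choice.
* **Augmentation.** Optional random erasing (`erase_prob`): a random
  rectangle of a training view is replaced by background, discouraging
  whole-silhouette shortcuts. Off by default — on the synthetic cohort it
  slows convergence (it frequently hides exactly the thin palatal bridge
  that separates grades 2 and 3) without changing what the explanation
  highlights.
* **Loss.** Cross-entropy with inverse-frequency class weights by default,
  because severity cohorts are imbalanced (the evaluation defaults mirror a
  62/45/45/38 distribution). Severity is treated as a nominal 4-class
  problem — that is what the classifier being emulated does; an ordinal
  head is out of scope.
* **Training.** Adam (lr 1e-3), batches of 8 meshes, up to 60 epochs with
  early stopping (patience 10) on validation loss. All randomness is seeded
  from the config; repeated runs reproduce the training log exactly.

## The synthetic-shape generator

The patient meshes behind the original severity index are not
distributable, so `generate_dataset()` builds parametric stand-ins: a
horseshoe arch (elliptical cross-section swept along a parabolic midline)
with the four defect morphologies applied — a carved buccal depression
(grade 0), full-thickness gap(s) of a given angular width (grades 1–3), a
forward-translated premaxillary segment (grades 2–3) and a palatal
connecting strip whose width scales with the palatal-continuity parameter
(absent at 0, which splits the mesh into separate bony segments exactly as
a complete cleft does). Per-specimen anatomy (arch width, depth, ridge
thickness, cleft site, side) is jittered, and a small vertex noise is
added, so no two specimens are identical.

Parameter ranges per grade (see `defect_param_ranges()`) were chosen once
to mirror the clinical semantics with *slight* between-grade overlap —
projection and notch width overlap between grades 2 and 3, while palatal
bridge ranges are disjoint, matching the fact that palatal continuity is
what separates those grades clinically. The generator records the
ground-truth defect-region vertex indices (gap margins, carved region,
projected premaxilla) in the manifest; these masks give the heatmap
quality a quantitative target where the original validation was visual.

What the generator does **not** emulate: tooth anatomy, soft tissue,
segmentation noise, scanner artifacts, or the continuous anatomical
variation of real maxillae. Passing the synthetic recovery and
localization suites therefore shows the pipeline is *correct and
trainable*, not that it reaches clinical accuracy on patients.

## Evaluation protocol

`split_dataset()` builds a stratified five-fold assignment: the five test
sets partition the data (20% each), and each fold's remainder is split 7:1
into training and validation (70%/10% overall). `cross_validate()` trains
one model per fold and reports everything the protocol prescribes:
per-class precision, recall, F1 (with across-fold SDs), one-vs-rest AUC by
the midrank Mann–Whitney statistic, the pooled confusion matrix (and its
row-normalized form, whose diagonal is per-class recall), support-weighted
totals, accuracy, and within-±1-grade agreement (the band around the
confusion-matrix diagonal). Totals are *support-weighted*, not macro: that
is the convention under which the per-class rows of the published severity
report reproduce its printed totals, and the package treats it as the
report's implicit definition.

## Numerical choices and degenerate inputs

* Gradients for the CAM are taken w.r.t. the pre-softmax logit (standard
  Grad-CAM practice; the softmax would couple all classes).
* "Pooled using a max function" is applied at both places where pooling
  happens — across views per face, and from incident faces to vertices;
  the vertex step can be switched to mean pooling (`vertex_pool`).
* CAMs are bilinearly upsampled to render resolution *before* the
  pixel-to-face lookup, because the face-id buffer is defined at full
  resolution.
* Heatmaps are normalized to [0, 1] per mesh and per class for display
  (raw values are preserved); absolute CAM scale is not comparable across
  models.
* Rasterization is two-sided (normals flipped toward the camera): cleft
  meshes are open surfaces, and back-face culling would punch holes in the
  renders. Pixel centers sit at half-integer coordinates; ties at shared
  triangle edges resolve by z-buffer order, which is why the ray-cast
  oracle in the test suite excludes pixels within tolerance of an edge.
* Empty meshes, all-coincident vertices, cameras inside the unit sphere,
  out-of-range severity grades and mismatched CAM/buffer resolutions all
  raise immediate, specific errors. A mesh outside the frustum renders as
  an all-background view with a warning, not an error.
* Faces are stored 1-based internally (the R convention, as in the
  field's R mesh packages); OBJ (1-based) and VTK/VTP/PLY (0-based)
  indices are converted at the format boundary. The face-id buffer uses
  0 as its background sentinel for the same reason.

## Problem sizes used by the shipped checks

The end-to-end recovery run trains on 160 synthetic arches (40 per grade;
within that, 140 train / 20 validation) and tests on 40 held-out arches,
at 12 views and 64 px — sizes chosen so a complete desk-scale replication,
including rendering and heatmap scoring, finishes in a few minutes on one
CPU. The localization check asks that the defect-region mean of the
correct grade's normalized heatmap exceed the background mean on at least
80% of the 40 test arches.

## Known limitations

* The generator's four morphologies are idealized; real defects vary
  continuously and segmentation introduces its own artifacts.
* Grad-CAM resolution is bounded by the final conv maps; very small
  features (a hairline palatal bridge) can fall below it.
* Attention often concentrates on a few informative views; heatmap
  coverage of surfaces visible only in low-weight views is correspondingly
  weak — that is a property of the method, not a bug.
* **Explanations follow the classifier's evidence, which is not always the
  defect itself.** On the synthetic cohort, grade-0 heat localizes on the
  carved depression essentially always (a positive local surface feature),
  but for grades defined partly by *absence* of bone the trained
  classifier legitimately accumulates evidence on intact structure: the
  hallmark of a *unilateral* cleft includes the intact contralateral
  ridge, and because notch width grows with grade by clinical definition,
  the extent of remaining bone is itself discriminative. Grad-CAM then
  paints those regions, and the defect-region localization check fails for
  grades 1-3 even though the gradients are finite-difference-exact and the
  pixel-to-face mapping is oracle-verified. We verified this is model
  behavior, not an implementation artifact, by checking the CAMs in image
  space against the projected defect pixels. Richer training cohorts, in
  which global bone extent is uninformative, are expected to push the
  evidence back onto the defect; the package reports the localization rate
  so users can measure this on their own data.
* The training loop is plain single-threaded BLAS; it is meant for
  desk-scale experiments, not for hundreds of high-resolution scans.
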