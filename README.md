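# cstt — care-assessment-aware activity recognition for older adults

Activity recognition in long-term care has a property that general-purpose
recognizers ignore: a resident's posture and movement are shaped by their
health condition. The same activity looks different at different assistance
levels, and different activities can look alike — leaning forward with hands
extended may be reaching over a meal tray or attempting to stand, and which
one it is depends on who is moving. Care facilities already quantify
assistance needs as a **care level** (CL), an integer 1–5 assigned by medical
professionals, grouped low (CL 1–2), mid (CL 3) and high (CL 4–5).

`cstt` implements a **care-assessment-aware spatiotemporal transformer
(CSTT)** that makes this context a first-class model input, plus everything
needed to study it end to end:

* **Model.** Per frame, 17 COCO keypoints (flattened to a 34-vector) and a
  64×64 depth heatmap (convolved and cut into 8×8 patches) are embedded into
  a shared latent space of dimension *d*. A **care-aware attention** block
  uses the embedded care level as the *sole query* over the concatenated
  keypoint/heatmap tokens,

  `Attention(Q, K, V) = softmax(QKᵀ/√d_h) V,  Q = C,  K = V = [K_kp, H]`,

  with 4 heads, so each frame becomes a care-weighted summary of its own
  features. Frame features get sinusoidal positional encoding (ρ = 10,000)
  and pass through a 2-layer pre-norm temporal transformer; mean pooling and
  a softmax layer yield probabilities over four activities (sitting, eating,
  stand up, trying to stand up). The care-blind baseline (**TSTT**) replaces
  the care query with a learned token; further ablation modes drop
  modalities or mask 30% of joints. The network, backpropagation and the
  AdamW-style optimizer are implemented in vectorized R; gradients are
  finite-difference-checked in the test suite.
* **Dataset validation statistics.** Mean per-joint angle difference (MPJAD),
  cosine dissimilarity of flattened motion vectors, and HOG similarity
  (canonical 8×8 cells / 2×2 blocks / 9 unsigned bins / L2-Hys) with pairwise
  tables across care groups and across activities.
* **Synthetic generator.** A deterministic, care-conditioned motion simulator
  (parametric archetypes in a virtual 640×640 frame, Gaussian-blob depth
  rendering) reproducing the structural facts the method relies on: posture
  degrades monotonically with care level, stand-up activities are absent in
  the high group, trying-to-stand is rarest, and eating ↔ trying-to-stand are
  confusable within the low/mid groups. A `care_interaction` mode generates
  data where the label is identifiable only from care × motion jointly.
* **Harness.** Cross-day (session-level) 80/20 splits, a fixed training
  recipe (batch 8, lr 0.001, weight decay 0.0005, 25 epochs), an ablation
  runner, one-vs-rest ROC/AUC, cumulative gains, per-care-group confusion
  matrices, and attention-weight export.

## Worked example

```r
library(cstt)

# 1. simulate a care-conditioned cohort (12 subjects, strong confusability)
spec <- generator_spec(n_subjects = 12, frames = 24, seed = 7, confusability = 0.9)
d <- generate_dataset(spec)
d
#> <har_dataset: 105 samples, 12 subjects, 5 sessions>

# 2. dataset validation: activity similarity between the mid and low groups
tab <- build_similarity_tables(d, "by_activity_within_groups")
dplyr::filter(tab, activity_mid == "eating")
#>   activity_mid activity_low       mpjad cosine_dissimilarity hog_similarity
#> 1 eating       sitting             0.21                 0              0.81
#> 2 eating       trying_to_stand_up  0.09                 0              0.88
#> 3 eating       stand_up            0.31                 0.01           0.73
```

Although eating and trying to stand are different activities, they are the
most similar pair on both angle statistics and gradient structure (MPJAD
0.09 rad vs. 0.21/0.31; HOG 0.88 vs. 0.81/0.73) — exactly the confusability
the care context is meant to resolve. (MPJAD averages over the 8 limb
joints; cosine dissimilarity of raw coordinate vectors is near 0 because
seated poses share most of their geometry.)

```r
# 3. train the care-aware model and evaluate across days
model <- cstt_train(d, cstt_config(), train_config(epochs = 10, seed = 1),
                    mode = "cstt")
glance(model)
#>   mode  n_params epochs final_loss train_fraction
#> 1 cstt    107150     10      0.281            0.8

report <- evaluate_model(model, d)   # test sessions only
report
#> <eval_report>
#>   precision recall    f1 accuracy
#> 1     0.876  0.857 0.863    0.929
#> micro AUC 0.995, macro AUC 0.989
round(report$attention, 3)
#>     keypoint heatmap
#> CL1    0.018   0.982
#> CL2    0.017   0.983
#> CL3    0.017   0.983
#> CL4    0.016   0.984
```

Ten epochs on this noisy, strongly confusable cohort already give 0.93
accuracy across held-out days, with the remaining errors concentrated in the
eating/trying pair. The exported care-attention matrix shows how the care
query distributes its mass between the keypoint token and the heatmap
patches per care level — the mechanism the model uses to condition on
care. On the care-interaction
condition (`generator_spec(..., care_interaction = TRUE)`), where motion
alone cannot identify the label, the care-aware model's macro-F1 exceeds the
care-blind TSTT's in 5 of 5 seeds (e.g. 1.00 vs. 0.77–0.95).

A thin command line sits over the same functions:

```sh
Rscript inst/cli/cstt.R simulate --spec spec.yaml --out data/ --seed 7
Rscript inst/cli/cstt.R validate --data data/ --mode activity --out tables.csv
Rscript inst/cli/cstt.R train    --data data/ --mode cstt --out model.ckpt
Rscript inst/cli/cstt.R eval     --model model.ckpt --data data/ --out report.json
Rscript inst/cli/cstt.R ablate   --data data/ --modes all --out ablation.csv
```

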