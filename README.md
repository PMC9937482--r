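# panogaze

Eye- and head-movement analysis for 360° panoramic viewing.

When observers explore omnidirectional scenes in a VR headset they move both
their eyes and their head. `panogaze` implements the full analysis chain for
such recordings across an encoding phase and an old/new recognition phase:

* **Spherical geometry** — great-circle metric, spherical (resultant-vector)
  means, quaternion algebra and shorter-arc slerp. All thresholds in the
  pipeline are angular distances on the stimulus sphere, never projected
  longitude/latitude differences, so nothing breaks near the poles.
* **Preprocessing** — head-pose quaternions (~70 Hz) are slerp-interpolated
  to the eye-tracker timestamps (250 Hz) and composed with the eye-in-head
  direction vectors: the *eye point* is the intersection of the world-frame
  eye vector with the sphere, the *head point* the intersection of the head's
  forward axis.
* **Fixation detection** — a dispersion-threshold (I-DT) algorithm adapted to
  spherical stimuli: a fixation is a window spanning ≥ 80 ms whose maximum
  pairwise great-circle distance stays ≤ 3°; its centroid is the spherical
  mean of the window. *Head fixations* are the spherical mean of head points
  over each eye fixation; saccade amplitudes, head shifts and the exploration
  tendency (mean great-circle distance from the first fixation) follow.
* **Spatial statistics** — per-trial spreads (SD of recentred longitudes and
  of latitudes, summarised as across-trial medians), equirectangular heatmaps
  built with an angular Gaussian kernel (σ = 4°), and heatmap correlations
  weighted by cos(latitude) — the exact inverse of the equirectangular area
  stretch — compared between same-scene and different-scene pairs.
* **Cross-recurrence analysis (CRA)** — two equal-length fixation sequences
  E (encoding) and R (recognition) define a binary matrix
  `r_ij = 1 ⇔ d(e_i, r_j) ≤ radius`; from it the nine scanpath-similarity
  measures REC, DET, hLAM, hTT, vLAM, vTT, CORM, CLUST and ENT are computed,
  with the radius calibrated by bisection so the mean recurrence across pairs
  hits a target (7% by default).
* **Study orchestration** — the four pairing conditions crossing
  same/different participant with same/different image (Sp-Si, Sp-Di, Dp-Si,
  Dp-Di), per-condition CRA summaries, a 2×2 repeated-measures ANOVA helper,
  and memory tables (Hit/Miss, CR/FA) with exact Mann–Whitney U contrasts.
* **Synthetic studies** — a generative model standing in for raw recordings:
  scenes are weighted von Mises–Fisher regions of interest with
  horizon-concentrated latitudes; fixation targets mix scene-driven and
  participant-idiosyncratic regions (weight ρ); the head orients toward the
  coarse region with reduced pitch, a lag and a smooth pursuit constant; the
  old/new response is a logistic function of realized exploration.

Everything is tibble-in / tibble-out and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` visualisations.

## A worked example

```r
library(panogaze)

cfg <- study_config(n_participants = 4, n_scenes_encoding = 10,
                    n_old = 5, n_new = 5, seed = 9L)
report <- run_pipeline(cfg)
glance(report)
```

```
# A tibble: 1 × 9
  n_trials n_fixations recognition_accuracy radius_eye radius_head
     <int>       <int>                <dbl>      <dbl>       <dbl>
1       80        2264                0.925       13.9        9.98
# i 4 more variables: spread_lon_encoding <dbl>, spread_lon_recognition <dbl>,
#   r_same_enc_rec_eye <dbl>, r_diff_enc_rec_eye <dbl>
```

Eighty simulated 10-s trials produce ~2300 fixations. Recognition accuracy
(0.925) sits near the high rate typical of panoramic scene memory (~0.92 by
design of the response model). The recurrence radius calibrated to 7% mean
recurrence is larger for the eyes (13.9°) than for the head (10.0°): head
points cluster more tightly than eye points, so a smaller radius already
captures the same proportion of recurrences. The last two columns show the
spatial encoding/recognition similarity: the mean same-scene heatmap
correlation (0.63) clearly exceeds the different-scene correlation (0.22).

Condition-level scanpath similarity and its figure:

```r
tidy(report)                 # condition x target x measure summary
plot_cra_summary(report$cra) # Sp-Si / Sp-Di / Dp-Si / Dp-Di panels
autoplot(make_heatmap(report$fixation_table$eye_lon,
                      report$fixation_table$eye_lat))
```

With the default idiosyncrasy weight (ρ = 0.2) this run's mean eye REC
values are 7.0 (Sp-Si), 3.2 (Sp-Di), 5.6 (Dp-Si) and 2.8 (Dp-Di): a strong
image effect, a weak participant effect.

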