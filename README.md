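# synmapr

Single-synapse quantification of fluorescent puncta for synaptome mapping.

Immunofluorescently labelled synaptic proteins appear in high-resolution
confocal micrographs (68 nm pixels, 12-bit data) as diffraction-limited
puncta, one per labelled terminal. Whether a marker such as the synaptic
vesicle protein **SV2A** — the target of widely used PET radiotracers —
labels *all* synapses or only a subpopulation is answered by comparing
puncta densities and colocalization across markers and brain regions.
`synmapr` implements that pipeline:

* **Simulation** — `generate_field()` renders multi-channel punctate fields
  with known ground truth: Poisson counts at density ρ per 100 µm², puncta
  as isotropic Gaussians A·exp(−r²/2σ²), per-channel colocalized or
  juxtaposed fractions, shot + read noise (SNR ≈ 10 by default).
* **Montage** — `tile_montage()` / `stitch_tiles()` reproduce no-overlap
  mosaic acquisition (942 × 920 px tiles) with bit-exact round trips.
* **Detection** — `detect_puncta()`: scale-normalised Laplacian-of-Gaussian
  filtering at σ = radius/√2, non-maximum suppression at one radius,
  quality and disc-mean intensity thresholds, sub-pixel refinement.
* **Quantification** — `puncta_density()` (100·count/area),
  `mean_puncta_intensity()`, subject-level mean ± SEM aggregation, and
  marker × region tables.
* **Colocalization** — `match_puncta()`: one-to-one cross-channel matching
  (distance-greedy, augmented to maximum cardinality), percentage of
  partner puncta containing the reference, and the analytic chance level
  1 − exp(−(ρ/100)·πd²) under spatial independence.
* **Reporting** — `build_fraction_table()` (reference density as a share of
  a summed denominator) and row-normalised, similarity-clustered heatmaps.

Reference marker tables (densities, intensities, colocalization
percentages for 7 mouse markers × 9 regions and 4 human markers × 6
cortical layers) are bundled as `ref_mouse_*()` / `ref_human_*()` and feed
both the table reconstruction and the simulator's density regimes.

## Worked example

Reconstructing the SV2A fraction tables from the bundled reference
densities (`analysis/01_reconstruct_fraction_tables.R`):

```
Mouse: SV2A vs VGLUT1 + VGAT
              CA1sr CA2sr CA3sr DGpo SMSL2/3 SMSL5 ENTIL4/5 STRcp THpo Mean
SV2A             19    18    18   16      18    17       18    16   15   17
VGLUT1 + VGAT    29    29    28   21      28    27       30    24   18   26
% SV2A           66    62    64   76      64    63       60    67   83   65
regional span: 60-83%
```

SV2A density never reaches the combined density of the excitatory
(VGLUT1) plus inhibitory (VGAT) presynaptic markers: depending on the
region, only 60–83% of presynaptic terminals can carry SV2A, and against
the postsynaptic markers (PSD95 + GPHN) the share drops to 29–40% in
mouse and 23–27% in human cortex — SV2A marks a subpopulation of
synapses, not all of them.

End-to-end validation on synthetic images
(`analysis/03_detect_and_quantify.R`), simulating one field per cell of
the 7 × 9 design at the reference densities and re-detecting:

```
pooled recall    0.970
pooled precision 1.000
per-cell |density error|: median 2.6%, max 5.6%
localisation RMSE 0.016 um (0.23 px)
```

Colocalization recovery and the independence null
(`analysis/04_colocalization.R`): configured paired fractions (67%, 69%
colocalized; 41%, 41% juxtaposed) are recovered within a percentage point
after chance correction, and with independent channels the observed
percentage matches the analytic chance level across distance criteria:

```
  max_dist_um observed_pct expected_pct mc_se_pct  n_B
1         0.2         1.07         1.25     0.166 4473
2         0.3         2.62         2.79     0.246 4473
3         0.5         7.56         7.56     0.395 4473
```

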