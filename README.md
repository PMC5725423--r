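# retinOS

Analysis and modelling toolkit for orientation selectivity (OS) in OFF OS
retinal ganglion cells — a cell type whose orientation tuning arrives
through **electrical synapses** (Cx36 gap junctions with an asymmetric
amacrine cell) rather than through oriented chemical inhibition.

The package is aimed at retinal electrophysiologists who need to:

* quantify drifting-grating responses (cycle averages, F1 amplitudes,
  vector-sum OSI/DSI and preferred angles, PSTH baseline / peak-offset
  rates, OFF OS and hOS/vOS classification, Hodges–Ajne and Hartigan-dip
  circular statistics);
* quantify dendritic-arbor asymmetry (polygon outlines, area, soma→centre-
  of-mass vectors, the dendritic orientation index, SWC I/O);
* dissect voltage-clamp currents (windowed peaks, IV curves,
  reversal-potential fits, the flat-IV signature of electrical coupling,
  conductance conversion, current subtraction, spike removal, Nernst / LJP
  utilities, spot-size tuning);
* drive a conductance-based leaky integrate-and-fire (LIF) model with
  cycle-averaged synaptic inputs and run the current-shuffling bootstrap
  that tests which input carries the orientation information.

Since no raw recordings are publicly deposited, a first-class synthetic
module (`gen_grating_currents()`, `gen_light_step_spikes()`,
`gen_morphology()`, `gen_iv_family()`, `gen_spot_size_series()`) generates
every input with the reported statistical structure, so the entire pipeline
is runnable and testable offline.

## The statistics at the core

For responses $R(\theta)$ at grating directions $\theta$:

$$\mathrm{OSI} = \frac{\left|\sum_\theta R(\theta) e^{2i\theta}\right|}{\sum_\theta R(\theta)},
\qquad
\mathrm{DSI} = \frac{\left|\sum_\theta R(\theta) e^{i\theta}\right|}{\sum_\theta R(\theta)},$$

with the preferred angle given by the phase (half the phase for OSI). The
same construction applied to centroid→perimeter vectors of the dendritic
outline gives the dendritic orientation index (DOI). The model is

$$\tau \dot V = V_\mathrm{rest} - V - R\,I_\mathrm{ext}, \qquad
I_\mathrm{ext} = I_\mathrm{gj} + (V - V_\mathrm{rev,inh})\,g_\mathrm{inh}(t),$$

with threshold/reset spiking and a temporarily increased τ as
refractoriness; outward current is positive and hyperpolarizing. The
shuffling bootstrap permutes per-angle input waveforms across angles
(10,000 draws by default) to destroy, selectively, the orientation
information carried by one input type.

## Worked example

```r
library(retinOS)

# a cosine tuning curve has OSI exactly 0.5 at its peak orientation
th <- seq(0, 330, by = 30)
curve <- tuning_curve(th, 1 + cos(2 * (th - 30) * pi / 180), unit = "spikes")
vector_sum_index(curve, order = 2)
#> $index
#> [1] 0.5
#> $preferred_deg
#> [1] 30
#> $preferred_reliable
#> [1] TRUE

# synthetic grating currents: gap-junction input tuned (OSI 0.4),
# inhibition untuned and ~10x larger; LIF model + shuffling bootstrap
gp  <- grating_params(osi_gj = 0.4, osi_inh = 0, seed = 7)
cur <- gen_grating_currents(gp)
cmp <- compare_conditions(lif_params(), cur$gj, cur$inh,
                          n_boot = 1000, seed = 11)
print(cmp$table, digits = 3)
#>      condition mean_osi sd_osi osi_of_mean_curve n_boot delta_vs_intact
#> 1       intact    0.441 0.0000           0.44118      1           0.000
#> 2  shuffle_inh    0.441 0.0000           0.44118   1000           0.000
#> 3   shuffle_gj    0.173 0.0820           0.00967   1000          -0.269
#> 4 shuffle_both    0.168 0.0833           0.00839   1000          -0.274
```

The model inherits its tuning from the gap-junction input: the intact model
is orientation selective (OSI 0.44, preferred angle = the generator's 90°),
shuffling the untuned inhibition changes nothing, and shuffling the
gap-junction currents collapses the tuning — the per-draw mean OSI falls
almost three-fold and the draw-averaged tuning curve is flat
(`osi_of_mean_curve` ≈ 0.01).

```r
# a ventrally displaced, elongated arbor like a vertical-preferring cell
arb <- gen_morphology(arbor_params(com_offset_um = c(0, -145),
                                   elongation = 2, orientation_deg = 90))
morphometrics(arb, "vOS-like")
#>    cell_id area_um2 com_len_um com_angle_deg    doi doi_angle_deg
#> 1 vOS-like    45239        145           270 0.3498            90
```

The end-to-end demo (`run_experiment()`) generates a 20-cell population,
classifies it from light-step spike trains, measures current tuning,
morphometrics and model tuning per cell, runs all four shuffle conditions,
and writes a byte-reproducible TSV/JSON bundle keyed to one master seed:

```r
bundle <- run_experiment(list(master_seed = 1, n_cells = 20, n_boot = 1000),
                         output_dir = "demo_out")
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It generates the synthetic population from the given seed, executes
classification, tuning, morphometrics, the LIF simulations and the
four-condition shuffling bootstrap, prints the population summary, and
writes the JSON report to `--out`.

## Package layout

| Area | Functions |
|---|---|
| containers | `trace()`, `cycle_set()`, `tuning_curve()`, `spike_trains()`, `arbor_polygon()` |
| tuning | `vector_sum_index()`, `cycle_average()`, `f1_amplitude()`, `psth()`, `baseline_rate()`, `peak_offset_rate()`, `classify_off_os()`, `classify_orientation_type()`, `orientation_angle_difference()` |
| circular stats | `hodges_ajne_test()`, `dip_statistic()`, `dip_test()` |
| morphology | `read_swc()`, `write_swc()`, `arbor_polygon()`, `compute_com()`, `compute_doi()`, `morphometrics()` |
| currents | `peak_current()`, `build_iv()`, `estimate_reversal()`, `subtract_currents()`, `conductance_from_current()`, `remove_spikes()`, `percent_change()`, `nernst()`, `ljp_correct()`, `normalize_iv()`, `size_tuning()` |
| model | `lif_params()`, `build_inputs()`, `simulate_lif()`, `grating_sweep()` |
| shuffle | `shuffle_spec()`, `shuffle_currents()`, `bootstrap_osi()`, `compare_conditions()` |
| synthetic data | `grating_params()`, `gen_grating_currents()`, `step_params()`, `gen_light_step_spikes()`, `arbor_params()`, `gen_morphology()`, `gen_iv_family()`, `gen_spot_size_series()`, `tuning_profile()` |
| pipeline | `validate_config()`, `run_experiment()` |

The methods vignette (`vignettes/off-os-circuit-model.Rmd`) documents the
models, conventions, synthetic-world calibrations and their limitations.
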