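# hdmeanet

Network analysis of developing neuronal cultures recorded on high-density
multielectrode arrays (HD MEAs), with a synthetic two-phenotype generator
for validating every stage against known ground truth.

## The problem

Dissociated cortical neurons on a 64 x 64 CMOS electrode grid (4096
electrodes, 42 um pitch, 10 kHz sampling) develop spontaneous network
activity over days in vitro (DIV): mean firing rates (MFR) rise,
interspike intervals (ISI) fall, synchronized population events -- network
bursts -- appear and multiply, and the functional network becomes
small-world-like.  Chronic amyloid-beta(1-42) oligomer exposure, an
Alzheimer's-disease model perturbation, derails this program: early
hyperactivity followed by decline, persistently localized firing,
abnormally high clustering on a fragmenting network, flat network-burst
counts, and fast, short, off-centre activity trajectories.

`hdmeanet` is aimed at electrophysiologists and computational
neuroscientists who need this analysis chain as tested, scriptable
building blocks rather than a vendor GUI:

- **Activity statistics** — per-electrode MFR maps, ISI distributions,
  quartile/SEM summaries, Welch's unpaired two-tailed t-test
  (`mean_firing_rate()`, `interspike_intervals()`, `average_isi_ratio()`,
  `welch_t_test()`).
- **Burst detection** — single-channel spike bursts by the max-interval
  rule (ISI <= 100 ms, >= 5 spikes), and population network bursts by a
  population-rate threshold (25 ms bins, mean + 3 SD, 100 ms merge gap,
  >= 10% of active electrodes) (`detect_bursts()`,
  `detect_network_bursts()`, `burst_stats()`).
- **Functional connectivity** — binned cross-correlograms (2 ms bins,
  +-25 ms lags) with spike-jitter surrogate significance (20 surrogates,
  mean + 4 SD); directed edges from the lag sign; sender/receiver/broker
  node roles (`cross_correlogram()`, `infer_graph()`,
  `classify_node_roles()`).
- **Graph metrics** — clustering coefficient `2T/(k(k-1))`,
  characteristic path length by BFS with 0.25-link histograms, node-degree
  distributions (`clustering_coefficient()`, `path_length_analysis()`,
  `degree_analysis()`, `graph_metrics()`).
- **Centre-of-activity trajectories (CAT)** — the activity-weighted
  centroid `CA(t) = sum_i n_i(t) p_i / sum_i n_i(t)` per 10 ms bin inside
  each network burst, summarised by velocity (mm/s), duration (ms),
  terminal distance from the arena centre and dispersion
  (`center_of_activity()`, `compute_cat()`, `cat_summary()`).
- **Synthetic phenotypes** — Poisson baselines plus embedded network
  bursts propagating along a ground-truth graph (control: growing
  small-world lattice, homogeneous firing; abeta42: dense off-centre
  modules, localized and fragmented activity), with the latent truth
  returned beside every raster (`phenotype_schedule()`,
  `simulate_recording()`).
- **Pipeline** — the full two-condition DIV-series experiment with long
  metrics tables, Welch comparisons and TSV/YAML outputs
  (`run_experiment()`, `compare_conditions()`).

All user-facing functions take and return tibbles (or light S3 wrappers
around tibbles) and compose with the pipe; result objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate one control recording at DIV16, detect its network bursts, and
trace the centre of activity through the first one:

```r
library(hdmeanet)

layout <- make_chip_layout(10, 10, 0.042)      # desk-scale grid, mm pitch
sched  <- phenotype_schedule("control")
sim    <- simulate_recording(sched[sched$div == 16, ], layout,
                             duration_s = 300, seed = 42)
sim$raster
#> <spike_raster> 192482 spikes on 100 electrodes, 300.0 s [control, DIV 16]

nb <- detect_network_bursts(sim$raster)
nrow(nb)                      # 55 embedded events, all recovered
#> [1] 55
burst_stats(nb, 300)[, 1:3]
#> # A tibble: 1 x 3
#>   count frequency_per_min mean_duration_ms
#>   <int>             <dbl>            <dbl>
#> 1    55                11              250

tr <- compute_cat(sim$raster, nb[1, ])
tr
#> <cat_trajectory> 20 points, 190 ms, 2.53 mm/s, terminal 0.024 mm

welch_t_test(mean_firing_rate(sim$raster)$mfr_hz,
             mean_firing_rate(simulate_recording(
               phenotype_schedule("abeta42")[6, ], layout, 300, 43)$raster)$mfr_hz,
             "control", "abeta42")
#> Welch t-test (control vs abeta42): t = 26.76, df = 197.93, p = 1.129e-67 ***
```

The numbers mean: all 55 embedded population events were recovered (11
events/min over 5 minutes, mean duration 250 ms); the first event's
centre-of-activity path moved at ~2.5 mm/s and ended 0.024 mm from the
arena centre (homogeneous firing converges on the centre); and at DIV16
the control MFR far exceeds the declining perturbed culture's.

The full two-condition experiment behind all figures:

```r
res <- run_experiment(out_dir = "results/demo")   # ~4 min on one CPU
dplyr::filter(res$metrics, metric == "n_network_bursts")
res$comparisons                                    # Welch tests per DIV
```

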