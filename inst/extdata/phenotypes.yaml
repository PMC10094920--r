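# Packaged phenotype schedules for the synthetic culture generator.
#
# One section per condition.  Condition-level keys apply to every DIV; the
# `divs` list holds the day-by-day parameters.  Units:
#   base_rate_hz            baseline (non-burst) firing rate per electrode, spikes/s
#   rate_dispersion         coefficient of variation of the per-electrode gamma
#                           rate multipliers (0 = identical electrodes)
#   n_network_bursts        synchronized population events embedded per recording
#   burst_participation     fraction of electrodes recruited per network burst
#   within_burst_rate_hz    firing rate of recruited electrodes inside a burst
#   burst_duration_mean_ms  mean embedded network-burst duration
#   burst_duration_rel_sd   sd of burst durations relative to the mean
#   spatial_profile         homogeneous | localized (Gaussian weight map)
#   spatial_center_*_rel    hotspot centre, as a fraction of the layout half-extent
#   spatial_width_rel       hotspot sd, as a fraction of the layout half-extent
#   propagation_delay_ms    burst-onset delay per ground-truth graph hop
#
# Control: steadily rising baseline rate, growing small-world graph
# (ring lattice + 10% rewiring, even mean degree rising with age), network
# bursts growing from 0 to 55 per 5-min recording, spatially homogeneous
# firing from DIV7 onwards.
#
# abeta42: baseline rate rises until DIV10 then declines, activity stays
# localized in an off-centre Gaussian hotspot at every age, the ground-truth
# graph is a union of dense modules (near-cliques) with two inter-module
# links, and network-burst counts stay flat at 25 per recording.  Within a
# network burst the activity is fragmented: firing alternates every
# module_alternation_ms between the hotspot module and the most distal
# module, producing the fast, disoriented, off-centre activity trajectories
# of the perturbed phenotype.
control:
  graph_type: smallworld
  rewiring_prob: 0.1
  within_burst_rate_hz: 60
  propagation_delay_ms: 5
  rate_dispersion: 0.3
  burst_duration_rel_sd: 0.08
  divs:
    - div: 1
      base_rate_hz: 0.5
      mean_degree: 2
      n_network_bursts: 0
      burst_participation: 0.4
      burst_duration_mean_ms: 400
      spatial_profile: localized
      spatial_center_x_rel: 0.0
      spatial_center_y_rel: 0.0
      spatial_width_rel: 0.8
    - div: 4
      base_rate_hz: 1.4014
      mean_degree: 4
      n_network_bursts: 10
      burst_participation: 0.5
      burst_duration_mean_ms: 350
      spatial_profile: localized
      spatial_center_x_rel: 0.0
      spatial_center_y_rel: 0.0
      spatial_width_rel: 0.8
    - div: 7
      base_rate_hz: 2.1
      mean_degree: 6
      n_network_bursts: 20
      burst_participation: 0.7
      burst_duration_mean_ms: 320
      spatial_profile: homogeneous
    - div: 10
      base_rate_hz: 2.6
      mean_degree: 8
      n_network_bursts: 35
      burst_participation: 0.8
      burst_duration_mean_ms: 300
      spatial_profile: homogeneous
    - div: 13
      base_rate_hz: 3.0
      mean_degree: 10
      n_network_bursts: 45
      burst_participation: 0.85
      burst_duration_mean_ms: 280
      spatial_profile: homogeneous
    - div: 16
      base_rate_hz: 3.5
      mean_degree: 12
      n_network_bursts: 55
      burst_participation: 0.9
      burst_duration_mean_ms: 260
      spatial_profile: homogeneous
abeta42:
  graph_type: modules
  inter_module_edges: 2
  within_burst_rate_hz: 45
  module_alternation_ms: 30
  propagation_delay_ms: 5
  rate_dispersion: 0.3
  burst_duration_rel_sd: 0.08
  divs:
    - div: 1
      base_rate_hz: 0.5
      n_network_bursts: 25
      burst_participation: 0.15
      burst_duration_mean_ms: 250
      spatial_profile: localized
      spatial_center_x_rel: 0.45
      spatial_center_y_rel: 0.33
      spatial_width_rel: 0.3
    - div: 4
      base_rate_hz: 0.781
      n_network_bursts: 25
      burst_participation: 0.15
      burst_duration_mean_ms: 220
      spatial_profile: localized
      spatial_center_x_rel: 0.45
      spatial_center_y_rel: 0.33
      spatial_width_rel: 0.3
    - div: 7
      base_rate_hz: 1.1
      n_network_bursts: 25
      burst_participation: 0.15
      burst_duration_mean_ms: 200
      spatial_profile: localized
      spatial_center_x_rel: 0.45
      spatial_center_y_rel: 0.33
      spatial_width_rel: 0.3
    - div: 10
      base_rate_hz: 1.4
      n_network_bursts: 25
      burst_participation: 0.15
      burst_duration_mean_ms: 190
      spatial_profile: localized
      spatial_center_x_rel: 0.45
      spatial_center_y_rel: 0.33
      spatial_width_rel: 0.3
    - div: 13
      base_rate_hz: 1.0
      n_network_bursts: 25
      burst_participation: 0.15
      burst_duration_mean_ms: 175
      spatial_profile: localized
      spatial_center_x_rel: 0.45
      spatial_center_y_rel: 0.33
      spatial_width_rel: 0.3
    - div: 16
      base_rate_hz: 0.6
      n_network_bursts: 25
      burst_participation: 0.15
      burst_duration_mean_ms: 160
      spatial_profile: localized
      spatial_center_x_rel: 0.45
      spatial_center_y_rel: 0.33
      spatial_width_rel: 0.3
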