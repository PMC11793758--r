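# Example configuration for `ocamorph run` / run_experiment().
# Units: mm. All seeds are explicit; reruns reproduce identical outputs.
arch:
  span: 50          # outer width at the posterior ends
  depth: 40         # anterior-posterior depth
  band_width: 8
  occlusal_height: 3
  resolution: 1.5   # target edge length; <= band_width / 4
scenario_w:         # 4 weeks wet storage (hydrated baseline -> W4)
  posterior_shrink: 0.07
  palatal_lift: 0.06
  buccal_retraction: 0.07
  smoothness: 10
scenario_d:         # 4 weeks dry storage, applied on top of the wet state
  posterior_shrink: 0.12
  palatal_lift: 0.10
  buccal_retraction: 0.12
  smoothness: 10
noise_sigma: 0.0279     # scanner precision (mm, per-vertex SD)
n_specimens: 8
specimen_variation: 0.2 # log-normal CV of per-specimen magnitudes
cutoff: 0.040           # mm; or set accuracy_report: <path to report.json>
seed: 1
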