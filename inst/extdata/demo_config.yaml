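# Demo run configuration for the middlemarks pipeline.
#
# Any key omitted here falls back to the package default shown by
# `run_config_template()`; unknown keys are rejected.

tail:
  name: H3_1-50
  residues: ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALRE
  first_position: 1
  cleavage_context: GluC after E50

# positions allowed to carry marks (the routinely interrogated H3 sites)
sites: [4, 8, 9, 14, 18, 23, 26, 27, 36]

# which kinds are allowed on which residues
mod_rules:
  me1: [K, R]
  me2: [K, R]
  me3: [K]
  ac: [K]

label_scheme:
  sequence_channel: false   # heavy-KR SILAC channel
  methyl_channel: false     # heavy-methyl (13CD3) counting
  allow_heavy_met: false

search:
  precursor_tol: 2.1        # Da
  fragment_tol: 0.01        # Da; below the 0.0364 Da me3/ac difference
  filter_ppm: 30            # localization-filter tolerance
  isobaric_window: 0.05     # Da window for co-isolated rivals
  max_mods: 3
  max_candidates: 50000
  min_score: 0.0

mixture:
  proteoforms:              # true composition; proportions sum to 1
    - {notation: K9me2, channel: light, proportion: 0.4}
    - {notation: K14me2, channel: light, proportion: 0.25}
    - {notation: K27me3, channel: light, proportion: 0.15}
    - {notation: "", channel: light, proportion: 0.2}
  noise:
    cv: 0.1                 # fragment intensity CV (log-normal)
    dropout: 0.05           # per-peak missing probability
    ppm_jitter: 2           # fragment mass jitter sd, ppm
  replicates: 1

seed: 42
sample: demo
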