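# Competitive (substrate-versus-decoy) sampling run: the decoy binds weaker
# by ddG = 1 kBT, both substrates are pushed uphill (+2 kBT) by the ion
# gradient (-4 kBT). Species codes must be quoted (YAML reads bare N/Y as
# booleans).
machine:
  conformations: {OF: outside, IF: inside}
  species:
    - {name: ion, code: 'N'}
    - {name: substrate, code: 'S', exclusive_group: sub}
    - {name: decoy, code: 'W', exclusive_group: sub, decoy_of: substrate}
environment:
  dmu: {ion: -4, substrate: 2, decoy: 2}
kinetics: {k0: 1.0e-3, split: 0.5, ddG: 1}
fitness: {kind: competitive, substrate: substrate, decoy: decoy}
mc:
  n_steps: 1000000
  thin: 500
  step_size: 1.0
analysis: {sweep_species: ion, sweep_from: -8, sweep_to: 0, sweep_step: 0.25}
seed: 1
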