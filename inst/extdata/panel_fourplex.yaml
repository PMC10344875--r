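# Four-analyte synthetic panel spanning seven orders of magnitude of
# testing concentration, with the assay context used in the package's
# simulations. All concentrations accept fM/pM/nM/uM suffixes.
context:
  reaction_volume: 50.0e-6
  sample_volume: 5.0e-6
  ligation_efficiency: 0.8
  bead_capacity: 10 nM
  mass_balance: yes
analytes:
  - name: IL6like
    epitope_count: 6
    kd_dab: 1 nM
    capture_efficiency: 0.9
    testing_range: [2 fM, 200 fM]
  - name: IL1RAlike
    epitope_count: 6
    kd_dab: 1 nM
    capture_efficiency: 0.9
    testing_range: [0.5 pM, 50 pM]
  - name: GDF15like
    epitope_count: 6
    kd_dab: 1 nM
    capture_efficiency: 0.9
    testing_range: [5 pM, 500 pM]
  - name: CRPlike
    epitope_count: 6
    kd_dab: 1 nM
    capture_efficiency: 0.9
    testing_range: [1 nM, 70 nM]
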