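# DSSO cross-linker definition (equivalent to the built-in).
#
# The sulfoxide C-S bonds cleave at low collision energy, leaving an alkene
# remnant (short/light arm) or a thiol remnant (long/heavy arm) on each
# peptide. Their mass difference, 31.9721 Da, is the doublet spacing
# observed in MS2 spectra.
name: DSSO
reactive_residues: K
nterm: true
short_arm:
  composition: C3H2O      # alkene, 54.01057 Da
long_arm:
  composition: C3H2OS     # thiol, 85.98264 Da
intact_composition: C6H6O3S   # 158.00376 Da added by the intact cross-link
# Optional alternative cleavage products / losses. Uncomment to search the
# corresponding shifted doublet spacings.
#products:
#  - label: water_loss
#    delta_mass: -18.0106
#    applies_to: both
#  - label: sulfenic_to_thiol
#    delta_mass: -18.0106    # sulfenic acid (103.9932) minus water = thiol
#    applies_to: long
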