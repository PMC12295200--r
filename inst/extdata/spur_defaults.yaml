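# Synthetic 1-ps track generator parameters (calibration starting points).
#
# initial_yields: molecules per 100 eV at 1 ps, literature-guided starting
# points for acidic water; H3Op mirrors e_aq (ionisation charge balance).
# sigma: Gaussian standard deviation (nm) of initial positions per class.
# mean_spur_energy: eV per spur for low-LET tracks.
# bounds: multiplicative calibration bounds on the 1-ps yields.
initial_yields:
  e_aq: 4.8
  H3Op: 4.8
  OH:   5.5
  H:    0.62
  H2:   0.15
  H2O2: 0.0
sigma:
  electron: 5.0
  radical:  0.85
mean_spur_energy: 40.0
yield_bounds: [0.6, 1.4]
sigma_bounds:
  electron: [2.0, 12.0]
  radical:  [0.3, 3.0]
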