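# Patchy-particle adsorption run: net-positive two-cap sphere at 5 mM.
# Units are embedded in the key names; omitted keys take package defaults
# (a = 70 A, N = 50, b = 2 A, r0 = 7 A, k = 0.5 N/m, n = 20, lmax = 10,
#  T = 298.15 K, eps_water = 78.7).
solution:
  salt_mM: 5
particle:
  sigma_p_Cm2: 0.03
  sigma_n_Cm2: 0.03
  theta_p_deg: 120
  theta_n_deg: 120
  eps_part: 78.7
protocol:
  equilibration_moves: 1000000
  sampling_interval: 1000
  n_samples: 10000
  seed: 1
  image_charges: no
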