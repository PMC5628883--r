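# Calibrated default parameters for the KRAS-coupled MAPK cascade model.
# Units: concentrations nM, time h; first-order rates 1/h, second-order
# rates 1/(nM h). Produced by scripts/calibrate.R; edit via that script,
# not by hand.
totals:
  GS: 100.0     # Grb2-SOS input level
  Ras: 200.0
  RAF: 100.0
  MEK: 500.0
  ERK: 1000.0
rates:
  k_act: 0.002      # GS-catalyzed Ras-GDP -> Ras-GTP, per nM GS_eff
  k_hyd: 10.0       # Ras-GTP hydrolysis (GAP-driven)
  k_rafact: 3.2     # Ras-GTP-catalyzed RAF activation
  k_rafdeact: 25.0
  k_fbraf: 0.0002   # ppERK feedback phosphorylation of active RAF
  k_recraf: 5.0
  k_mekp: 0.3       # RAF*-catalyzed MEK phosphorylation
  k_mekdp: 8.0
  k_fbmek: 0.0002   # ppERK feedback phosphorylation of MEK
  k_recmek: 5.0
  k_erkp: 0.2       # pMEK-catalyzed ERK phosphorylation (each step)
  k_erkdp: 29000.0  # basal ERK phosphatase Vmax (nM/h, each step)
  km_erk: 1500.0    # shared phosphatase Michaelis constant (nM)
  k_dusp: 290.0     # DUSP-catalyzed ERK dephosphorylation, per nM DUSP
  vmax_dusp: 100.0   # ppERK-induced DUSP synthesis (Hill)
  k_half_dusp: 325.0
  kdeg_dusp: 0.462  # half-life 1.5 h
  vmax_spry: 80.0
  k_half_spry: 325.0
  kdeg_spry: 0.555  # half-life 1.25 h
  k_spry: 2.2       # SPRY inhibition constant on Grb2-SOS
  hill_fb: 6.0      # effective cooperativity of the multi-gene feedback panel
inhibitors:
  mek: {kon: 0.04, koff: 0.4}    # Kd = 10 nM, slow-binding kinetics
  erk: {kon: 0.04, koff: 1.2}   # Kd = 30 nM, slow-binding kinetics
link:
  emax: 0.95
  k_rel: 0.25
  hill: 2.0
  mode: auc
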