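rates:
  cACE: 54.1
  cchym: 1.1
raas:
  k_prod: 0.975
  k_degI: 2.714
  k_degII: 1.458
  R0: 31.3
  tau_renin: 30.0
  ALD0: 196.3
  tau_ald: 60.0
  AT1_ref: 5.3
  K_at1: 2.5
  n_at1: 2.5
  at1_gain: 1.0
  g_renin_at1: 1.92
  g_renin_vol: 4.0
  g_ald: 0.355
cardiac:
  HR0: 75.0
  c0: 1.0
  Ed_lv: 0.0677
  Es_lv: 4.72
  Ed_rv: 0.0534
  Es_rv: 0.548
  E_sa0: 0.9
  E_sv: 0.0264
  E_pa: 0.1216
  E_pv: 0.0362
  V0_lv: 5.0
  V0_sa: 550.0
  V0_sv: 3183.0
  V0_rv: 10.0
  V0_pa: 60.0
  V0_pv: 350.0
  R_mv: 0.006
  R_av: 0.04
  R_tv: 0.005
  R_puv: 0.005
  PVR: 0.097
  Es_scale: 1.0
  Ts_coef: 0.388
  dt: 0.00025
vascular:
  SVR0: 1.369
  g_svr: 0.8
baro:
  MAP_ref: 126.08
  g_hr: 1.2
  g_c: 0.4
renal:
  Ra0: 65.23
  Re0: 32.25
  R_rest: 12.5
  g_aff: 0.05
  g_eff: 0.45
  g_tgf: 0.45
  g_myo: 1.0
  Kf: 3.12
  P_bowman_onc: 23.7
  P_ven: 4.0
  d_aff0: 13.7
  d_eff0: 18.7
  dyn_per_mmHgminL: 80.0
sodium:
  Na_ref: 143.6
  phi_sodin: 0.1
  fe0: 0.007439944766
  g_pn: 7.0
  h_at1: 2.2
  h_ald: 1.2
  MAP_ref_fe: 126.08
  g_osm: 0.02
volume:
  V_ecf_ref: 15.0
  bv_frac: 0.333333333333
scales:
  R0_scale: 1.0
  ALD0_scale: 1.0
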