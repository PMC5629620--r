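# Best-fit parameter set of the bundled pulse-chase study (hours).
# Shape parameters other than the neuroblast stage, the apoptotic-stage
# minimum and the NSC-phase minima were not reported by the fit; they are
# fixed at the midpoints of the corresponding search ranges.
influx_anp: 1.0
influx_nsc: 1.0
min_div_anp: 1
max_div_anp: 4
p_anp: 0.1
t_g1_anp_mean: 12.0
t_g1_anp_shape: 9.0
t_g1_anp_min: 3.0
t_s_anp_mean: 12.0
t_s_anp_shape: 22.0
t_s_anp_min: 4.0
t_g2m_anp_mean: 1.0
t_g2m_anp_shape: 12.0
t_g2m_anp_min: 0.5
t_anp_nb_mean: 12.0
t_anp_nb_shape: 9.0
t_anp_nb_min: 3.0
t_anp_apop_mean: 48.0
t_anp_apop_shape: 9.0
t_anp_apop_min: 2.0
t_nb_mean: 260.0
t_nb_shape: 2.0
t_nb_min: 20.0
t_in_mean: 120.0
t_in_shape: 2.0
t_in_min: 20.0
t_apop_mean: 1.4
t_apop_shape: 9.0
t_apop_min: 0.15
t_g1_nsc_mean: 28.0
t_g1_nsc_shape: 9.0
t_g1_nsc_min: 3.5
t_s_nsc_mean: 11.0
t_s_nsc_shape: 22.0
t_s_nsc_min: 2.5
t_g2m_nsc_mean: 3.0
t_g2m_nsc_shape: 12.0
t_g2m_nsc_min: 0.375
d_g1: 0.14
d_s: 0.0
d_g2m: 0.02
d_anp: 0.33
d_nb: 0.97
d_in: 0.0
min_div_nsc: 2
max_div_nsc: 5
p_nsc: 0.57
include_in: no
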