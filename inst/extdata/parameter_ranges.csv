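param,kind,lo,hi,values
min_div_anp,set,NA,NA,1;2;3
max_div_anp,set,NA,NA,2;3;4;5;6;7;8
p_anp,range,0,1,NA
t_g1_anp_mean,range,6,20,NA
t_g1_anp_shape,range,2,16,NA
t_g1_anp_min,range,2,5,NA
t_s_anp_mean,range,5,12,NA
t_s_anp_shape,range,5,40,NA
t_s_anp_min,range,1,4,NA
t_g2m_anp_mean,range,1,4,NA
t_g2m_anp_shape,range,5,20,NA
t_g2m_anp_min,range,0,0.75,NA
t_anp_nb_mean,range,4,64,NA
t_anp_nb_shape,range,2,16,NA
t_anp_nb_min,range,0,3,NA
t_anp_apop_mean,range,4,64,NA
t_anp_apop_shape,range,2,16,NA
t_anp_apop_min,range,0,3,NA
t_nb_mean,range,120,430,NA
t_nb_shape,range,2,16,NA
t_nb_min,range,10,80,NA
t_apop_mean,range,0.4,3,NA
t_apop_shape,range,2,16,NA
t_apop_min,range,0,0.3,NA
d_g1,range,0,0.99,NA
d_s,range,0,0.99,NA
d_g2m,range,0,0.99,NA
d_anp,range,0,0.99,NA
d_nb,range,0,0.99,NA
min_div_nsc,set,NA,NA,1;2;3
max_div_nsc,set,NA,NA,2;3;4;5;6
p_nsc,range,0,1,NA
t_g1_nsc_mean,range,8,36,NA
t_g1_nsc_shape,range,2,16,NA
t_g1_nsc_min,range,2,5,NA
t_s_nsc_mean,range,5,12,NA
t_s_nsc_shape,range,5,40,NA
t_s_nsc_min,range,1,4,NA
t_g2m_nsc_mean,range,1,4,NA
t_g2m_nsc_shape,range,5,20,NA
t_g2m_nsc_min,range,0,0.75,NA
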