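"name","value","units","provenance"
"D_mmp",1e-14,"m2 s-1","calibrated"
"D_aga",1e-14,"m2 s-1","default"
"D_agg",1e-13,"m2 s-1","default"
"D_aggd",1e-12,"m2 s-1","default"
"D_cold",1e-12,"m2 s-1","default"
"alpha_mmp",3e-06,"s-1","calibrated"
"alpha_aga",3e-06,"s-1","default"
"k_mmp",3.5e-22,"mol","paper"
"k_aga",3.5e-22,"mol","default"
"k_rate_mmp",3.6e-05,"s-1","paper"
"k_rate_aga",3.6e-05,"s-1","default"
"k_mmp_cold",2e-04,"m3 mol-1 s-1","calibrated"
"n_R_cold",10,"1","default"
"k_mmp_catalytic",1.5,"s-1","paper"
"K_m_mmp",0.15,"mol m-3","calibrated"
"k_basal",2.032433e-07,"s-1","calibrated"
"k_act",3e-05,"mol m-3","paper"
"n_hill",2,"1","default"
"k_aga_catalytic",1.5,"s-1","default"
"K_m_aga",0.15,"mol m-3","default"
"h_agg",1e-09,"m s-1","default"
"h_aggd",1e-08,"m s-1","default"
"h_mmp",1e-11,"m s-1","calibrated"
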