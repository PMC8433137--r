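term,estimate,sd,t
intercept,0.970,0.0348,27.86
distance,0.005,0.0002,23.07
technique_em,-0.064,0.0202,-3.19
method_registration_free,0.188,0.0202,9.31
method_surface_based,0.197,0.0202,9.78
distance_x_technique_em,-0.001,0.0003,-2.35
distance_x_method_registration_free,-0.001,0.0003,-3.13
distance_x_method_surface_based,-0.003,0.0003,-9.73
technique_em_x_method_registration_free,-0.253,0.0286,-8.87
distance_x_technique_em_x_method_registration_free,0.000,0.0004,0.86
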