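{"permeability":{"true_PD":1e-06,"P_D":9.63186001302418e-07,"r_squared":0.99986478046818,"diameter_um":158,"status":"ok"},"morphometry":{"ki67_fraction":0.2,"ki67_truth":0.2,"mean_junctional_score":0.568046738661232,"expected_junctional_score":0.6,"mean_golgi_angle":67.5000000426887,"status":"ok"},"secretome":{"relative_secretion":{"CK1":3,"CK2":1,"CK3":1,"CK4":1,"CK5":1,"CK6":0.5,"CK7":1,"CK8":1,"CK9":1,"CK10":1,"CK11":1,"CK12":1},"expected":{"CK1":3,"CK2":1,"CK3":1,"CK4":1,"CK5":1,"CK6":0.5,"CK7":1,"CK8":1,"CK9":1,"CK10":1,"CK11":1,"CK12":1},"status":"ok"},"mechanics":{"E_true":130,"E_mean":130.263418732867,"E_sd":1.2668402408947,"n":6,"status":"ok"},"transport":{"mass_conservation_error":8.20850897465576e-07,"gradient_time_to_half_s":239.764101320765,"midpoint_steady":0.499999999999998,"status":"ok"},"stats":{"test":"one-way ANOVA + Bonferroni pairwise","statistic":24.5,"p_value":5.79573428383378e-05,"pairwise":{"group1":["mutant_a","mutant_b","mutant_b"],"group2":["control","control","mutant_a"],"p_raw":[5.65254343067709e-05,1,5.65254343067709e-05],"p_adjusted":[0.000169576302920313,1,0.000169576302920313]},"status":"ok"}}
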