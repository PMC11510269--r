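theta_direct	alpha_true	beta2_true	total	pm_true	outlier_rsids	pleiotropic_rsids
-0.19	-0.44	0.19	-0.2736	0.305555555555556		
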