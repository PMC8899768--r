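name,value,units,provenance
total_gastric_emptying_volume,700,ml,reconstructed
total_secretions_volume,2333,ml,reconstructed
total_si_emptying_volume,500,ml,reconstructed
total_colon_emptying_volume,50,ml,reconstructed
gastric_half_emptying_time,110,min,published
gastric_shape,1.81,1,published
tau_gastric,240,min,published
tau_si,240,min,reconstructed
tau_colon,1920,min,reconstructed
k_si_fluid_abs,0.01,1/min,reconstructed
k_colon_fluid_abs,0.0013,1/min,reconstructed
vmax,1.98,umol/h/1e9 cells,reconstructed
km,2,mM,reconstructed
activity_cap_downstream,0.75,1,published
scf_rate,0.2,umol/h/1e9 cells,published
o2_gastric,0.07,1,reconstructed
o2_si,0.04,1,reconstructed
o2_colon,0,1,reconstructed
ph_fed,6.7,pH,reconstructed
ph_fasted,2,pH,published
ph_half_time,110,min,published
ph_shape,1.81,1,published
f_abs_a,0.035,1,reconstructed
f_abs_b,0.004,day/mg,reconstructed
f_abs_c,0.06,1,reconstructed
eh_multiplier,4,1,published
f_si_abs,0.6,1,reconstructed
r_endogenous,0.000118344315685829,mmol/min,reconstructed
k_urinary,0.000694444444444444,1/min,reconstructed
n_daily_meals,3,1,published
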