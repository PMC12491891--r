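quantity,value
mean_e,0.0065
ci_e_lower,-0.0219
ci_e_upper,0.0349
mean_c,-46359
ci_c_lower,-111696
ci_c_upper,18977
lambda,500000
lambda_max,1000000
users_per_year,988
horizon_years,5
discount_rate,0.03
app_maintenance_cost,24000
app_development_cost,194855
app_downloads,1976
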