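variable,test,mean_sor,sd_sor,n_sor,mean_nosor,sd_nosor,n_nosor,yes_sor,yes_nosor,published_p
population,welch_t_log,6900000,7600000,34,5700000,6700000,16,,,0.585
urban_pct,welch_t,75.4,14,34,69.7,15.4,16,,,0.219
minority_pct,welch_t,31.2,17.1,34,31.4,13,16,,,0.962
poverty_pct,welch_t,12.9,2.95,34,13.4,2.85,16,,,0.550
uninsured_pct,welch_t,7.5,2.62,34,9.5,3.54,16,,,0.056
opioid_rx_per100,welch_t,59.9,14.1,34,68.9,21.8,16,,,0.148
misuse12plus_pct,welch_t,4.55,0.762,34,4.68,0.72,16,,,0.551
misuse12_17_pct,welch_t,3.66,1.14,34,4.49,1.03,16,,,0.015
misuse18_25_pct,welch_t,8.21,1.62,34,8.32,1.85,16,,,0.840
misuse26plus_pct,welch_t,4.05,0.86,34,4.07,0.72,16,,,0.926
admissions_per100k,welch_t,214,229,34,134,127,16,,,0.131
deaths_per100k,welch_t,19.5,10.7,34,16,9.03,16,,,0.245
sor_dollars_per_person,welch_t,4.29,3.79,34,3.36,2.61,16,,,0.318
mm_clinics_per100k,welch_t,0.61,0.41,34,0.50,0.49,16,,,0.433
misuse_per_mm_center_per100k,welch_t,8.12,4.28,34,11.7,7.13,16,,,0.082
rx_physicians_per100k,welch_t,18.20,7.93,34,15.9,9.84,16,,,0.413
medicaid_expansion,yates_chi2,,,34,,,16,27,9,0.173
moud_covered,yates_chi2,,,34,,,16,27,13,0.988
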