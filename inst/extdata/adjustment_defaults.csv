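# Default definitional adjustment ratios (alternative definition : GA28).
# GA22 means are published comparison values (1.5 HIC, 1.2 LMIC pool).
# Variances and the BW1000/BW500 rows are placeholders; replace them with
# estimates from paired data for production use (n_pairs = NA marks a
# placeholder row).
definition,income_class,ratio_mean,ratio_var,n_pairs
GA22,HIC,1.5,0.0225,NA
GA22,LMIC_POOL,1.2,0.0324,NA
BW1000,HIC,1.0,0.01,NA
BW1000,LMIC_POOL,1.0,0.01,NA
BW500,HIC,1.3,0.04,NA
BW500,LMIC_POOL,1.3,0.04,NA
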