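country_code,year,nmr,nmr_se
C01,2000,15.5660816135866,0.77830408067933
C01,2001,15.4797436628549,0.773987183142744
C01,2002,15.1263131270116,0.756315656350581
C01,2003,14.7389514509001,0.736947572545004
C01,2004,14.4389780188452,0.721948900942258
C01,2005,14.2464853795502,0.712324268977509
C01,2006,14.1776681554131,0.708883407770656
C01,2007,14.2487752533531,0.712438762667653
C01,2008,14.4404401680308,0.722022008401539
C01,2009,13.8453209127034,0.692266045635172
C02,2000,6.20287490542997,0.310143745271499
C02,2001,6.04666817921702,0.302333408960851
C02,2002,5.93761324578756,0.296880662289378
C02,2003,5.80823955595744,0.290411977797872
C02,2004,5.64076445648391,0.282038222824196
C02,2005,5.46230594945643,0.273115297472822
C02,2006,5.29398482572672,0.264699241286336
C02,2007,5.13521403041589,0.256760701520794
C02,2008,4.97662939536795,0.248831469768397
C02,2009,4.71840763824653,0.235920381912326
C03,2000,19.9089391791143,0.995446958955716
C03,2001,19.1460284899534,0.957301424497672
C03,2002,18.5557152968714,0.927785764843569
C03,2003,18.0097258078652,0.90048629039326
C03,2004,17.4881088935898,0.87440544467949
C03,2005,17.063764774214,0.853188238710701
C03,2006,16.766832501241,0.838341625062048
C03,2007,16.4683014157686,0.823415070788432
C03,2008,16.0118838185623,0.800594190928116
C03,2009,15.2936886248026,0.764684431240128
C04,2000,24.3578706504575,1.21789353252287
C04,2001,24.2105712822374,1.21052856411187
C04,2002,23.3058378371902,1.16529189185951
C04,2003,22.3712609006359,1.11856304503179
C04,2004,21.6166998583605,1.08083499291802
C04,2005,20.8115138136881,1.04057569068441
C04,2006,19.8541571620244,0.99270785810122
C04,2007,19.0916925950695,0.954584629753475
C04,2008,18.8834023268093,0.944170116340465
C04,2009,18.5319290636335,0.926596453181675
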