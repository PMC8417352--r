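country_code,year,true_log_rate
C01,2000,-4.38580453870553
C01,2001,-4.39136652151897
C01,2002,-4.41446301183312
C01,2003,-4.44040508236804
C01,2004,-4.46096747365449
C01,2005,-4.47438859403391
C01,2006,-4.47923076873674
C01,2007,-4.47422787440847
C01,2008,-4.46086621474564
C01,2009,-4.50295149498189
C02,2000,-5.30588595129415
C02,2001,-5.33139142413135
C02,2002,-5.34959158814273
C02,2003,-5.371621307764
C02,2004,-5.40087923204158
C02,2005,-5.4330277946326
C02,2006,-5.46432759281086
C02,2007,-5.49477730708028
C02,2008,-5.52614599665079
C02,2009,-5.57942745239746
C03,2000,-4.13972999444763
C03,2001,-4.17880352573645
C03,2002,-4.21012098643944
C03,2003,-4.23998689566273
C03,2004,-4.26937767212093
C03,2005,-4.2939416341371
C03,2006,-4.3114961511776
C03,2007,-4.32946142343689
C03,2008,-4.35756764509027
C03,2009,-4.4034585951857
C04,2000,-3.93804380299706
C04,2001,-3.94410946267156
C04,2002,-3.98219495015497
C04,2003,-4.02312169068606
C04,2004,-4.05743267273547
C04,2005,-4.09539244800565
C04,2006,-4.14248541627295
C04,2007,-4.18164553252528
C04,2008,-4.19261547782672
C04,2009,-4.21140369052644
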