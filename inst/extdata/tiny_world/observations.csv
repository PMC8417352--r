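country_code,year,sbr_observed,definition,source_type,n_total_births,n_stillbirths,nmr_same_source,unknown_ga_fraction,livebirth_coverage,child_death_completeness
C01,2000,16.5374932122229,GA22,ADMIN,283598,4690,16.3258208182294,0.0912535300012678,0.993965929052792,0.97998579274863
C01,2001,20.1780025362655,GA22,ADMIN,258648,5219,14.4077564794667,0.157681537908502,0.908335071098991,0.993963297258597
C01,2002,11.979818783941,GA28,ADMIN,269954,3234,15.7161605682956,0.028708134253975,0.949939819951542,0.998958679195493
C01,2003,12.0771091739949,GA28,ADMIN,260410,3145,13.2477332414917,0.0249101468361914,0.918192583722994,0.982506433571689
C01,2004,11.5110604798259,GA28,ADMIN,235252,2708,14.7384792330623,0.0637768362648785,0.831149376383983,0.994719671679195
C01,2005,15.316031554147,GA22,ADMIN,275463,4219,15.480794378312,0.149118011700921,0.975164682879113,0.867300117900595
C01,2006,10.1225405222632,GA22,ADMIN,233637,2365,14.0286102500055,0.189790366974194,0.828755393442698,0.958283912355546
C01,2007,11.5021689924369,GA28,ADMIN,238129,2739,14.7814717525741,0.129642403044272,0.846383030973375,0.957721748412587
C01,2008,11.2771887741055,GA28,ADMIN,265137,2990,13.9972950030324,0.19798671832541,0.944263298362493,0.971216734533664
C01,2009,17.960922404339,GA22,ADMIN,268082,4815,13.5249870976119,0.170240754145198,0.95666647054255,0.955349734344054
C02,2000,2.50616752163527,GA28,ADMIN,255370,640,5.99874142917191,0.159021131985355,0.826986867613159,0.999652264104225
C02,2001,7.33767516663143,GA22,ADMIN,288511,2117,6.83926609500645,0.0791404031333514,0.93618107907474,0.971698779077269
C02,2002,4.51736947228911,GA28,ADMIN,267855,1210,5.92121919541938,0.110443537472747,0.870897560548037,0.973845959431492
C02,2003,4.60332062257964,GA28,ADMIN,269588,1241,5.99262679351217,0.0660269762156531,0.878287964286283,0.986066678666975
C02,2004,6.8926833632716,GA22,ADMIN,290598,2003,5.91800642302309,0.12497599737253,0.948633749578148,0.998240207950585
C02,2005,4.457350725588,GA28,ADMIN,256206,1142,5.82556394009983,0.0550082149566151,0.83804128378164,0.978035392554011
C02,2006,2.08922302649974,GA28,ADMIN,257512,538,5.21016305264441,0.187182457186282,0.843999982476234,0.883192021306604
C02,2007,3.96135984154561,GA28,ADMIN,295858,1172,5.56355544561127,0.191380119649693,0.971622786815278,0.960127424146049
C02,2008,5.65022483474128,GA22,ADMIN,289546,1636,4.84654811898494,0.0494979817303829,0.95279898787383,0.956909142027143
C02,2009,3.68431194062577,GA28,ADMIN,301006,1109,4.82563533032041,0.237071106210351,0.992497290577739,0.976763452775776
C03,2000,16.2946433572387,GA28,ADMIN,446343,7273,19.2711563748929,0.240724206028972,0.835774463531561,0.949228579411283
C03,2000,16.8428953164511,GA28,STUDY,6686,NA,19.607848860071,0.00275226024677977,NA,NA
C03,2004,20.0463319798309,GA22,ADMIN,464474,9311,16.570055439688,0.0480873134802096,0.869723409009166,0.976106237026397
C03,2005,13.6479496892798,GA28,ADMIN,497071,6784,15.9081360271638,0.0603006422170438,0.930761933880858,0.968886839959305
C03,2005,8.63576790182295,GA22,HMIS,419650,3624,NA,0.15144843456801,0.785792201105505,NA
C03,2006,14.5934243594953,GA28,HMIS,465141,6788,NA,0.0428853370249271,0.870973436888307,NA
C03,2007,13.1116031147877,GA28,ADMIN,527548,6917,16.8503362087372,0.0797241072286852,0.98782898269128,0.953052995342296
C03,2008,6.97635201968266,GA28,SURVEY,7407,NA,16.5749855480339,0.230886615579948,NA,NA
C03,2009,16.6689542311144,GA22,ADMIN,473575,7894,14.2073565966334,0.0240368225495331,0.886765854917467,0.970047006045934
C03,2009,14.2724263339584,GA28,HMIS,465513,6644,NA,0.227643728081603,0.87166955367662,NA
C04,2003,17.5760058346904,UNSPECIFIED,ADMIN,500455,8796,21.8951469026885,0.124096759420354,0.989229646320455,0.953620093932841
C04,2004,17.1820090617748,GA28,ADMIN,452450,7774,21.947749639911,0.163516984321177,0.894340999824926,0.970537741167936
C04,2004,7.28999346132806,GA28,SURVEY,4311,NA,21.470938190831,0.0148766916245222,NA,NA
C04,2005,16.6639927012718,GA28,ADMIN,417607,6959,20.0776681777829,0.0673278497415595,0.825467866933905,0.987525991094299
C04,2005,9.17601428335442,UNSPECIFIED,HMIS,441913,4055,NA,0.0156865829485469,0.87351195929572,NA
C04,2006,19.3144506662263,GA22,ADMIN,466283,9006,20.8455643083242,0.19962024257984,0.92168389915023,0.993378437624779
C04,2006,14.742603123823,GA28,HMIS,430114,6341,NA,0.0426180534414016,0.850190376099199,NA
C04,2006,26.7451164688775,GA22,SURVEY,3531,NA,20.1707427855263,0.147178800019901,NA,NA
C04,2007,13.9582443983361,GA28,HMIS,402916,5624,NA,0.58615101177711,0.796429169438779,NA
C04,2007,13.5985924936397,GA28,SURVEY,11224,NA,19.3859326214819,0.642273045750335,NA,NA
C04,2008,7.57112970217865,GA28,ADMIN,423979,3210,19.4560210373136,0.783799562114291,0.83806376195047,0.984815458301455
C04,2008,12.6185790663943,GA28,HMIS,401947,5072,NA,0.141002065618522,0.794514127420262,NA
C04,2009,15.4492959173336,GA28,HMIS,473808,7320,NA,0.186182324017864,0.936558385696262,NA
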