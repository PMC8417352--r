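country_code,year,source_type,definition,true_log_rate,def_ratio,def_err,bias,src_err,corrupt
C01,2000,ADMIN,GA22,-4.38580453870553,1.5,-0.133623665489315,0,0.00700748818440034,FALSE
C01,2001,ADMIN,GA22,-4.39136652151897,1.5,0.10857748536799,0,0.00403774904715714,FALSE
C01,2002,ADMIN,GA28,-4.41446301183312,1,0,0,-0.0115085556562711,FALSE
C01,2003,ADMIN,GA28,-4.44040508236804,1,0,0,0.00495619641604594,FALSE
C01,2004,ADMIN,GA28,-4.46096747365449,1,0,0,-0.0106813120068717,FALSE
C01,2005,ADMIN,GA22,-4.47438859403391,1.5,-0.120158243010894,0,-0.00466116096375502,FALSE
C01,2006,ADMIN,GA22,-4.47923076873674,1.5,0.125848166459556,0,0.012488636888101,TRUE
C01,2007,ADMIN,GA28,-4.47422787440847,1,0,0,-0.0119849585655778,FALSE
C01,2008,ADMIN,GA28,-4.46086621474564,1,0,0,0.00969545013970117,FALSE
C01,2009,ADMIN,GA22,-4.50295149498189,1.5,0.0573751697483578,0,0.000458035797250989,FALSE
C02,2000,ADMIN,GA28,-5.30588595129415,1,0,0,0.00824073963681881,TRUE
C02,2001,ADMIN,GA22,-5.33139142413135,1.5,0.0273695272430415,0,-0.00687596841243412,FALSE
C02,2002,ADMIN,GA28,-5.34959158814273,1,0,0,-0.0162561673921129,FALSE
C02,2003,ADMIN,GA28,-5.371621307764,1,0,0,-0.0124639549803204,FALSE
C02,2004,ADMIN,GA22,-5.40087923204158,1.5,0.0163416319486097,0,-0.0123671423510935,FALSE
C02,2005,ADMIN,GA28,-5.4330277946326,1,0,0,0.000315731875532431,FALSE
C02,2006,ADMIN,GA28,-5.46432759281086,1,0,0,-0.0138702655355974,TRUE
C02,2007,ADMIN,GA28,-5.49477730708028,1,0,0,0.00275456968739591,FALSE
C02,2008,ADMIN,GA22,-5.52614599665079,1.5,-0.0453397511229793,0,0.0118753427862908,FALSE
C02,2009,ADMIN,GA28,-5.57942745239746,1,0,0,-0.00153357890661644,FALSE
C03,2000,ADMIN,GA28,-4.13972999444763,1,0,0,0.0144635652537848,FALSE
C03,2000,STUDY,GA28,-4.13972999444763,1,0,0,0.0471107993311305,FALSE
C03,2004,ADMIN,GA22,-4.26937767212093,1.2,0.16447701646676,0,0.00442013088178811,FALSE
C03,2005,ADMIN,GA28,-4.2939416341371,1,0,0,-0.00998738655996004,FALSE
C03,2005,HMIS,GA22,-4.2939416341371,1.2,0.267700720973257,0,-0.227698465336006,TRUE
C03,2006,HMIS,GA28,-4.3114961511776,1,0,0,0.0866650172377294,FALSE
C03,2007,ADMIN,GA28,-4.32946142343689,1,0,0,0.0043839703617272,FALSE
C03,2008,SURVEY,GA28,-4.35756764509027,1,0,-0.1,-0.0375097680109528,TRUE
C03,2009,ADMIN,GA22,-4.4034585951857,1.2,0.142597758745783,0,-0.00585011508633235,FALSE
C03,2009,HMIS,GA28,-4.4034585951857,1,0,0,0.159774317864858,FALSE
C04,2003,ADMIN,UNSPECIFIED,-4.02312169068606,1,0,0,-0.00035414564917612,FALSE
C04,2004,ADMIN,GA28,-4.05743267273547,1,0,0,0.00143289764040456,FALSE
C04,2004,SURVEY,GA28,-4.05743267273547,1,0,-0.1,-0.215884394748297,TRUE
C04,2005,ADMIN,GA28,-4.09539244800565,1,0,0,0.00562451973173495,FALSE
C04,2005,HMIS,UNSPECIFIED,-4.09539244800565,1,0,0,0.107312743858427,TRUE
C04,2006,ADMIN,GA22,-4.14248541627295,1.2,0.0204014328620591,0,-0.00720153544943125,FALSE
C04,2006,HMIS,GA28,-4.14248541627295,1,0,0,-0.0496995556316686,FALSE
C04,2006,SURVEY,GA22,-4.14248541627295,1.2,-0.0535359984183581,-0.1,0.229992073824344,FALSE
C04,2007,HMIS,GA28,-4.18164553252528,1,0,0,-0.0821700029230871,FALSE
C04,2007,SURVEY,GA28,-4.18164553252528,1,0,-0.1,-0.168273390953283,FALSE
C04,2008,ADMIN,GA28,-4.19261547782672,1,0,0,0.0136219726875099,TRUE
C04,2008,HMIS,GA28,-4.19261547782672,1,0,0,-0.184054378061069,FALSE
C04,2009,HMIS,GA28,-4.21140369052644,1,0,0,0.0362580202906029,FALSE
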