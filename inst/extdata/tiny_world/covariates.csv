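country_code,year,nmr,lbw,anc4,csec,edu,gni
C01,2000,5.19135980421762,0.102603239006409,1,0.307088076281607,17.5102627018737,97916.0289404647
C01,2001,5.12131622640644,0.101966094392929,1,0.298375163644159,17.5903607688043,98377.2677222919
C01,2002,5.05221770017665,0.101332906313984,0.962222785977753,0.320502860187929,17.670458835735,98840.6791944964
C01,2003,4.98405147457351,0.100703650200323,0.984424224663653,0.340402566498818,17.7505569026657,99306.2735916544
C01,2004,4.91680497068244,0.100078301635265,0.987333573272127,0.353241539881309,17.8306549695963,99774.0611965527
C01,2005,4.85046577930784,0.0994568363537537,1,0.336018699714164,17.910753036527,100244.052340416
C01,2006,4.78502165868314,0.0988392302414106,0.984314941571679,0.343784482964103,17.9908511034576,100716.257403134
C01,2007,4.72046053221182,0.0982254593336044,0.936870891581905,0.334759331701412,18.0709491703883,101190.686813492
C01,2008,4.6567704862389,0.0976154998145186,0.94119066142849,0.363025721863239,18.151047237319,101667.3510494
C01,2009,4.59393976785242,0.0970093280162278,1,0.358058585316892,18.2311453042496,102146.260638127
C02,2000,3.59949060905129,0.074848914153384,0.777030402637886,0.191821516107194,9.86301494957021,60167.1772078661
C02,2001,3.50085074842872,0.0746789244584119,0.778780561789131,0.182747227705163,9.90867829406707,61077.6846691954
C02,2002,3.40491399865166,0.0745093208277765,0.814256249600317,0.208326245970699,9.95434163856394,62001.9708031435
C02,2003,3.31160628410609,0.0743401023846854,0.797650165471018,0.200981317488764,10.0000049830608,62940.2441218061
C02,2004,3.22085555913416,0.0741712682543376,0.797909918250387,0.197433284556399,10.0456683275577,63892.7162926844
C02,2005,3.13259175240565,0.0740028175639186,0.84702317678277,0.20128453922213,10.0913316720545,64859.6021864352
C02,2006,3.04674671281374,0.0738347494425963,0.835230229867485,0.20729527356858,10.1369950165514,65841.1199253443
C02,2007,2.9632541568536,0.0736670630215165,0.893431395751866,0.20338406793263,10.1826583610482,66837.4909325331
C02,2008,2.88204961744287,0.0734997574337981,0.869011723591397,0.174538191894122,10.2283217055451,67848.9399819103
C02,2009,2.80307039414471,0.0733328318145287,0.903844882437931,0.20930127591977,10.273985050042,68875.695248879
C03,2000,6.90708491847196,0.0985433632933335,0.969137621228643,0.395930963918549,9.78828837530703,9953.67905393812
C03,2001,6.75540825888811,0.0980774047446015,0.988196272267786,0.388607426789095,9.91885113289595,9999.05892790937
C03,2002,6.60706235451201,0.0976136494631611,1,0.392136933298646,10.0494138904849,10044.6456935184
C03,2003,6.4619740633699,0.0971520870309464,0.970929532844553,0.395267884224934,10.1799766480738,10090.4402940061
C03,2004,6.32007184965479,0.0966927070791533,0.979143423708523,0.389757879241994,10.3105394056627,10136.4436769136
C03,2005,6.18128574845573,0.0962354992880061,1,0.413045455767278,10.4411021632516,10182.656794102
C03,2006,6.04554733126158,0.0957804533865256,1,0.409978406922684,10.5716649208406,10229.080601772
C03,2007,5.91278967222231,0.0953275591522988,0.999275351770803,0.415546556910104,10.7022276784295,10275.7160604837
C03,2008,5.78294731515123,0.0948768064112487,0.972284474051806,0.43193190585241,10.8327904360184,10322.5641351767
C03,2009,5.65595624125177,0.0944281850374063,0.968004382027043,0.436040492265056,10.9633531936073,10369.6257951897
C04,2000,13.9612843053554,0.0695161430211856,1,0.239546435006251,6.78212115079198,4013.26498358902
C04,2001,13.7601789143839,0.0688954863616929,1,0.247366853472947,6.81151405525893,4031.33444954452
C04,2002,13.5619703470421,0.068280371072481,0.969935827063203,0.247920539513661,6.84090695972588,4049.48527210149
C04,2003,13.3666168760194,0.067670747678878,1,0.25422148624385,6.87029986419282,4067.71781756279
C04,2004,13.1740773750662,0.0670665671479336,0.976664531824844,0.249141432430183,6.89969276865977,4086.0324538805
C04,2005,12.9843113103363,0.0664677808844755,0.992110276249121,0.268417851639194,6.92908567312672,4104.42955066338
C04,2006,12.7972787318536,0.0658743407272004,0.981554882362623,0.273603452007755,6.95847857759367,4122.90947918435
C04,2007,12.6129402651013,0.0652861989448008,0.987552996560901,0.312237630268583,6.98787148206062,4141.47261238796
C04,2008,12.4312571027334,0.0647033082321255,0.99376386069003,0.278086323631839,7.01726438652757,4160.11932489789
C04,2009,12.2521909964044,0.0641256217063751,0.99238321915994,0.299568813807924,7.04665729099452,4178.84999302457
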