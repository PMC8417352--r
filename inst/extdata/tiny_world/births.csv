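# livebirths_unit: thousands
country_code,year,livebirths,region_code,income_group
C01,2000,285.319953779427,R1,HIC
C01,2001,284.749313871868,R1,HIC
C01,2002,284.179815244124,R1,HIC
C01,2003,283.611455613636,R1,HIC
C01,2004,283.044232702409,R1,HIC
C01,2005,282.478144237004,R1,HIC
C01,2006,281.91318794853,R1,HIC
C01,2007,281.349361572633,R1,HIC
C01,2008,280.786662849488,R1,HIC
C01,2009,280.225089523789,R1,HIC
C02,2000,308.795905962725,R1,HIC
C02,2001,308.1783141508,R1,HIC
C02,2002,307.561957522498,R1,HIC
C02,2003,306.946833607453,R1,HIC
C02,2004,306.332939940238,R1,HIC
C02,2005,305.720274060358,R1,HIC
C02,2006,305.108833512237,R1,HIC
C02,2007,304.498615845213,R1,HIC
C02,2008,303.889618613522,R1,HIC
C02,2009,303.281839376295,R1,HIC
C03,2000,534.047616761257,R2,UMIC
C03,2001,534.047616761257,R2,UMIC
C03,2002,534.047616761257,R2,UMIC
C03,2003,534.047616761257,R2,UMIC
C03,2004,534.047616761257,R2,UMIC
C03,2005,534.047616761257,R2,UMIC
C03,2006,534.047616761257,R2,UMIC
C03,2007,534.047616761257,R2,UMIC
C03,2008,534.047616761257,R2,UMIC
C03,2009,534.047616761257,R2,UMIC
C04,2000,505.90350340892,R2,UMIC
C04,2001,505.90350340892,R2,UMIC
C04,2002,505.90350340892,R2,UMIC
C04,2003,505.90350340892,R2,UMIC
C04,2004,505.90350340892,R2,UMIC
C04,2005,505.90350340892,R2,UMIC
C04,2006,505.90350340892,R2,UMIC
C04,2007,505.90350340892,R2,UMIC
C04,2008,505.90350340892,R2,UMIC
C04,2009,505.90350340892,R2,UMIC
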