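ratio
0.745783190769073
0.6643930243222
0.799069097978852
0.709506317682247
0.738475464634182
0.970453040481753
0.77921176195949
0.68119211260579
0.819826522572227
0.75763441358872
0.874029178287015
0.991753924792079
0.689321548619867
0.856461419433137
0.810252912406762
0.915020587486466
0.772896392662421
0.906965659654552
0.615757580832333
1.03073824361902
0.910804636217083
0.782109948162146
0.643717946019414
0.881004763349095
0.860136250265588
0.799237688259818
0.818382729454192
0.732889823888746
0.845503863287573
0.836151551727542
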