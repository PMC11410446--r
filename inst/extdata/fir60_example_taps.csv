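# domain=z fs=360
numerator
-4.168e-19
0.0004528
-0.0008864
0.001208
-0.00127
0.0009014
-5.451e-18
-0.001371
0.002909
-0.004086
0.004272
-0.002955
3.791e-17
0.004159
-0.008473
0.01146
-0.01158
0.00778
-2.215e-17
-0.01052
0.02122
-0.02865
0.02921
-0.02005
2.962e-17
0.02986
-0.06616
0.1037
-0.1364
0.1587
0.8331
0.1587
-0.1364
0.1037
-0.06616
0.02986
2.962e-17
-0.02005
0.02921
-0.02865
0.02122
-0.01052
-2.215e-17
0.00778
-0.01158
0.01146
-0.008473
0.004159
3.791e-17
-0.002955
0.004272
-0.004086
0.002909
-0.001371
-5.451e-18
0.0009014
-0.00127
0.001208
-0.0008864
0.0004528
-4.168e-19
denominator
1
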