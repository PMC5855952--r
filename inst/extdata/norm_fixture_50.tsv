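value
1.291842
2.241184
0.447179
1.28159
0.842522
3.940939
0.403604
0.746594
2.255667
1.661733
1.20757
0.364626
1.101297
4.347431
1.300151
5.668959
4.02153
0.657057
2.346168
1.779993
1.144725
0.135332
1.056752
3.2292
1.41264
1.512284
0.311145
0.769068
2.904685
2.820334
0.57637
1.407789
0.336205
1.094637
2.57596
0.431671
0.151656
2.839332
2.095885
0.569126
3.092548
0.848084
0.928055
4.232071
0.211542
0.440294
2.85786
1.225583
2.204352
0.022579
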