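condition,source,pct
5,Gene,59.3910
5,Tissue,13.3032
5,Interaction,25.7179
5,IPCA1,83.0273
5,IPCA2,16.9680
8,Gene,58.460
8,Tissue,8.890
8,Interaction,28.490
8,IPCA1,93.666
8,IPCA2,5.197
13,Gene,14.709
13,Tissue,23.833
13,Interaction,61.018
13,IPCA1,95.584
13,IPCA2,4.254
18,Gene,8.473
18,Tissue,25.024
18,Interaction,64.308
18,IPCA1,99.715
18,IPCA2,0.280
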