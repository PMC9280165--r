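condition,view,ordering
5,mean,AFP1>YB-1>CIRP>HMGB1
5,stability,AFP1>CIRP>HMGB1>YB-1
5,comprehensive,AFP1>YB-1>CIRP>HMGB1
5,discrimination,Muscle>Skin
8,mean,AFP1>HMGB1>YB-1>CIRP
8,stability,CIRP>AFP1>YB-1>HMGB1
8,comprehensive,AFP1>HMGB1>CIRP>YB-1
8,discrimination,Spleen>Kidney
13,mean,AFP1>YB-1>HMGB1>CIRP
13,stability,CIRP>HMGB1>AFP1>YB-1
13,comprehensive,AFP1>YB-1>HMGB1>CIRP
13,discrimination,Muscle>Skin
18,mean,YB-1>AFP1>HMGB1>CIRP
18,stability,CIRP>HMGB1>AFP1>YB-1
18,comprehensive,YB-1>AFP1>HMGB1>CIRP
18,discrimination,Muscle>Skin
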