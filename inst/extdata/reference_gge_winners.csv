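condition,tissue,winner
5,Brain,AFP1
5,Heart,AFP1
5,Intestine,AFP1
5,Kidney,AFP1
5,Liver,AFP1
5,Muscle,AFP1
5,Spleen,AFP1
5,Skin,AFP1
5,Gonad,AFP1
8,Brain,AFP1
8,Heart,AFP1
8,Intestine,AFP1
8,Kidney,AFP1
8,Liver,AFP1
8,Muscle,AFP1
8,Spleen,AFP1
8,Skin,AFP1
8,Gonad,AFP1
13,Brain,AFP1
13,Heart,AFP1
13,Intestine,AFP1
13,Kidney,AFP1
13,Liver,AFP1
13,Muscle,YB-1
13,Spleen,AFP1
13,Skin,AFP1
13,Gonad,AFP1
18,Brain,AFP1
18,Heart,YB-1
18,Intestine,AFP1
18,Kidney,AFP1
18,Liver,AFP1
18,Muscle,YB-1
18,Spleen,AFP1
18,Skin,AFP1
18,Gonad,YB-1
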