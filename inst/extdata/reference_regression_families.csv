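gene,tissue,family
AFP1,Brain,power
AFP1,Heart,power
AFP1,Intestine,power
AFP1,Kidney,power
AFP1,Liver,power
AFP1,Muscle,power
AFP1,Spleen,power
AFP1,Skin,power
AFP1,Gonad,power
CIRP,Brain,poly3
CIRP,Intestine,poly3
CIRP,Kidney,poly3
CIRP,Liver,poly3
CIRP,Muscle,poly2
CIRP,Spleen,poly2
CIRP,Skin,poly2
CIRP,Gonad,poly2
HMGB1,Brain,poly3
HMGB1,Heart,poly3
HMGB1,Intestine,poly3
HMGB1,Kidney,poly3
HMGB1,Liver,poly2
HMGB1,Muscle,poly3
HMGB1,Spleen,poly3
HMGB1,Skin,poly3
HMGB1,Gonad,poly3
YB-1,Brain,poly3
YB-1,Heart,poly3
YB-1,Intestine,poly3
YB-1,Kidney,poly3
YB-1,Liver,poly3
YB-1,Muscle,poly3
YB-1,Spleen,poly2
YB-1,Skin,poly3
YB-1,Gonad,poly2
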