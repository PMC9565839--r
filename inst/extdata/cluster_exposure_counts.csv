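cluster,unexposed,exposed
C0,1,31
C1,3,20
C2,5,23
C3,0,1
C4,0,4
C5,16,17
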