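variable,group,n,mean,sd
height_cm,exposed,96,163.95,7.89
height_cm,unexposed,25,169.96,8.15
weight_kg,exposed,96,63.11,10.94
weight_kg,unexposed,25,71.76,12.06
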