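element,energy_ev
B,-670
N,-1485
Al,-6600
Cu,-44820
C,-1030
H,-13.6
O,-2045
S,-10830
Cl,-12520
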