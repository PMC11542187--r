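host,guest,complex,E_BSSE,flag
B12N12,Cad,B12N12-Cad,0,
CuB11N12,Cad,CuB11N12-Cad,0,
B12N11Cu,Cad,B12N11Cu-Cad,0,
Cu(b64)B12N12,Cad,Cu(b64)B12N12-Cad,0,
Cu(b66)B12N12,Cad,Cu(b66)B12N12-Cad,0,
Cu@B12N12,Cad,Cu@B12N12-Cad,0,
Al12N12,Cad,Al12N12-Cad,0,
CuAl11N12,Cad,CuAl11N12-Cad,0,
Al12N11Cu,Cad,Al12N11Cu-Cad,0,
Cu(b64)Al12N12,Cad,Cu(b64)Al12N12-Cad,0,
Cu(b66)Al12N12,Cad,Cu(b66)Al12N12-Cad,0,
Cu@Al12N12,Cad,Cu@Al12N12-Cad,0,
Cu(b64)B12N12,NO,Cu(b64)B12N12-NO,0,
Cu(b64)B12N12,H2O,Cu(b64)B12N12-H2O,0,
Cu(b64)B12N12,H2,Cu(b64)B12N12-H2,0,
Cu(b64)B12N12,H2S,Cu(b64)B12N12-H2S,0,
Cu(b64)B12N12,CO,Cu(b64)B12N12-CO,0,
Cu(b64)B12N12,COCl2,Cu(b64)B12N12-COCl2,0,baseline_unprinted
Cu(b64)B12N12,N2O,Cu(b64)B12N12-N2O,0,
Cu(b64)B12N12,N2,Cu(b64)B12N12-N2,0,
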