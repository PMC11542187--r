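label,wavelength_nm,f,energy_ev,assignment,weight_pct,flag
B12N12,174.4,0.039,7.1,H(a)->L(a),58,
B12N12,198.1,0.16,6.3,H(a)->L(a),39,
Cu(b64)B12N12,212,0.012,5.8,H(b)->L(b),28,
Cu(b64)B12N12,250.8,0.27,4.8,H(a)->L(a),94,energy_mismatch
Cu(b64)B12N12,332.1,0.031,3.7,H(a)->L(a),91,
Cu(b64)B12N12-Cad,215.6,0.011,5.7,H(a)->L(a),28,
Cu(b64)B12N12-Cad,350,0.12,3.5,H(a)->L(a),90,
Cu(b64)B12N12-Cad,373.3,0.026,3.3,H(a)->L(a),60,
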