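complex,phi,phi_ads,dphi_pct,Q_Cu_ads,Q_guest,dG_ads,E_ads,flag
B12N12-Cad,4.19,3.21,23.39,NA,NA,-1.01,-1.55,
CuB11N12-Cad,5.86,4.98,15.02,0.431,0.293,-1.35,-1.67,
B12N11Cu-Cad,3.78,2.99,20.9,-0.166,0.237,-0.95,-1.18,
Cu(b64)B12N12-Cad,3.25,2.46,24.31,0.257,0.2,-1.26,-1.39,
Cu(b66)B12N12-Cad,3.18,2.15,32.39,0.206,0.198,-0.96,-1.02,
Cu@B12N12-Cad,4.13,3.3,20.1,-0.306,0.354,-1.3,-1.81,
Al12N12-Cad,4.42,3.91,11.54,NA,NA,-1.25,-1.72,
CuAl11N12-Cad,3.51,2.98,14.98,0.279,0.246,-1.12,-1.27,dphi_inconsistent
Al12N11Cu-Cad,3.91,3.26,16.62,-0.336,0.289,-1.07,-1.16,
Cu(b64)Al12N12-Cad,3.45,2.58,25.22,0.137,0.237,-0.97,-1.07,
Cu(b66)Al12N12-Cad,3.42,2.55,25.44,0.146,0.243,-0.95,-1,
Cu@Al12N12-Cad,4.69,4.05,13.65,0.156,0.33,-1.4,-1.9,
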