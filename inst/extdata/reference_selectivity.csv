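guest,complex,E_gap,channel,dgap_pct,S,kappa,E_ads,phi_ads,dphi_pct,S_j,kappa_j,flag
Cad,Cu(b64)B12N12-Cad,4.25,alpha,39.8,17000000000,1,-1.39,2.46,24.31,22000000000000,1,
NO,Cu(b64)B12N12-NO,1.94,alpha,36.18,2000000000,8.5,-1.25,3.37,3.69,110,210000000000,
H2O,Cu(b64)B12N12-H2O,4.09,alpha,34.54,740000000,22.5,-0.79,2.87,11.69,2600000,8500000,
H2,Cu(b64)B12N12-H2,4.03,alpha,32.57,230000000,72.2,-0.05,2.75,15.38,280000000,80000,
H2S,Cu(b64)B12N12-H2S,3.99,alpha,31.25,110000000,160,-0.6,2.85,12.31,5700000,3900000,
CO,Cu(b64)B12N12-CO,2.48,alpha,18.42,54000,310000,-1.09,3.25,0,0,NA,
COCl2,Cu(b64)B12N12-COCl2,4.95,beta,18.42,3200000,5200,-0.91,4.53,2.79,160,140000000000,baseline_unprinted
N2O,Cu(b64)B12N12-N2O,3.45,alpha,13.49,2900,5700000,-0.72,3.38,4,160,140000000000,
N2,Cu(b64)B12N12-N2,2.78,alpha,8.55,160,110000000,-0.48,3.5,7.69,17000,1300000000,
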