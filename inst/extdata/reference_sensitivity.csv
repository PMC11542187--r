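label,channel,E_H_iso,E_L_iso,E_gap_iso,E_H_ads,E_L_ads,E_gap_ads,d_gap,dgap_pct,flag
B12N12,restricted,-7.63,-0.76,6.87,-6.57,0.15,6.72,0.15,2.18,
CuB11N12,alpha,-6.89,-4.84,2.05,-6.34,-3.63,2.7,0.65,31.71,
B12N11Cu,alpha,-5.16,-2.4,2.76,-4.39,-1.59,2.8,0.04,1.45,
Cu(b64)B12N12,alpha,-4.78,-1.73,3.04,-4.58,-0.34,4.25,1.21,39.8,
Cu(b66)B12N12,alpha,-4.74,-1.62,3.12,-4.08,-0.22,3.86,0.74,23.72,
Cu@B12N12,alpha,-6.91,-1.34,5.57,-6.14,-0.46,5.68,0.11,1.97,
Al12N12,restricted,-6.42,-2.43,3.99,-5.89,-1.93,3.97,0.02,0.5,
CuAl11N12,alpha,-4.45,-2.56,1.89,-3.97,-2,1.96,0.07,3.7,
Al12N11Cu,alpha,-4.92,-2.9,2.02,-4.42,-2.1,2.32,0.3,14.85,
Cu(b64)Al12N12,alpha,-4.62,-2.28,2.35,-3.37,-1.79,1.58,0.77,32.77,
Cu(b66)Al12N12,alpha,-4.53,-2.32,2.22,-3.27,-1.84,1.43,0.79,35.59,
Cu@Al12N12,beta,-6.27,-3.12,3.15,-5.58,-2.53,3.05,0.1,3.17,
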