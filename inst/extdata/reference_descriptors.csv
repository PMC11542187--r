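label,eta,mu,omega,dipole,Q_Cu,flag
B12N12,3.43,-4.19,2.56,0,NA,
CuB11N12,1.02,-5.86,16.78,1.26,0.37,
B12N11Cu,1.38,-3.78,5.16,2.07,0.02,omega_rounding
Cu(b64)B12N12,1.52,-3.25,3.48,1.43,0.14,
Cu(b66)B12N12,1.56,-3.18,3.25,1.67,0.14,
Cu@B12N12,2.78,-4.13,3.06,2.88,0.04,
Al12N12,2,-4.42,4.9,0.02,NA,
CuAl11N12,0.95,-3.51,5.84,0.8,0.2,omega_inconsistent
Al12N11Cu,1.01,-3.91,7.55,2.65,-0.34,omega_rounding
Cu(b64)Al12N12,1.17,-3.45,5.07,1.52,0.06,omega_rounding
Cu(b66)Al12N12,1.11,-3.42,5.29,2.31,0.05,omega_rounding
Cu@Al12N12,1.57,-4.69,6.99,1.67,0.58,
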