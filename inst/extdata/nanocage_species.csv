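label,role,formula,E_total,G_free,dipole,multiplicity,channel,E_H,E_L,charges
B12N12,host,B12N12,-26037.6,-26036.1,0,1,restricted,-7.625,-0.7550000000000003,NA
CuB11N12,host,CuB11N12,-70175.6,-70174.1,1.26,2,alpha,-6.885,-4.835000000000001,Cu=0.37
B12N11Cu,host,B12N11Cu,-69358.2,-69356.7,2.07,2,alpha,-5.16,-2.4,Cu=0.02
Cu(b64)B12N12,host,B12N12Cu,-70857.5,-70856,1.43,2,alpha,-4.77,-1.73,Cu=0.14
Cu(b66)B12N12,host,B12N12Cu,-70856.25,-70854.75,1.67,2,alpha,-4.74,-1.62,Cu=0.14
Cu@B12N12,host,B12N12Cu,-70845,-70843.5,2.88,2,alpha,-6.915,-1.3449999999999998,Cu=0.04
Al12N12,host,Al12N12,-97159.44,-97157.94,0.02,1,restricted,-6.415,-2.425,NA
CuAl11N12,host,CuAl11N12,-135369.6,-135368.1,0.8,2,alpha,-4.455,-2.565,Cu=0.20
Al12N11Cu,host,Al12N11Cu,-140483.4,-140481.9,2.65,2,alpha,-4.92,-2.9000000000000004,Cu=-0.34
Cu(b64)Al12N12,host,Al12N12Cu,-141980,-141978.5,1.52,2,alpha,-4.625,-2.2750000000000004,Cu=0.06
Cu(b66)Al12N12,host,Al12N12Cu,-141978.75,-141977.25,2.31,2,alpha,-4.53,-2.3099999999999996,Cu=0.05
Cu@Al12N12,host,Al12N12Cu,-141970,-141968.5,1.67,2,beta,-6.265000000000001,-3.115,Cu=0.58
Cad,guest,C5H14N2,-2140,-2138,1.68,1,restricted,-6.205,2.205,NA
NO,guest,NO,-1130,-1128,NA,2,alpha,-7,-2,NA
H2O,guest,H2O,-2075,-2073,NA,1,restricted,-8.3,1.9,NA
H2,guest,H2,-32,-30,NA,1,restricted,-9.2,2.3,NA
H2S,guest,H2S,-10860,-10858,NA,1,restricted,-7,1.5,NA
CO,guest,CO,-3080,-3078,NA,1,restricted,-9,0.5,NA
COCl2,guest,COCl2,-28600,-28598,NA,1,restricted,-8,-1,NA
N2O,guest,N2O,-5010,-5008,NA,1,restricted,-8.5,0.4,NA
N2,guest,N2,-2980,-2978,NA,1,restricted,-9.5,1.6,NA
B12N12-Cad,complex,B12N12C5H14N2,-28179.149999999998,-28175.109999999997,NA,1,restricted,-6.57,0.1499999999999999,NA
CuB11N12-Cad,complex,CuB11N12C5H14N2,-72317.27,-72313.45000000001,NA,2,alpha,-6.33,-3.6300000000000003,Cu=0.431;guest=0.293
B12N11Cu-Cad,complex,B12N11CuC5H14N2,-71499.37999999999,-71495.65,NA,2,alpha,-4.390000000000001,-1.5900000000000003,Cu=-0.166;guest=0.237
Cu(b64)B12N12-Cad,complex,B12N12CuC5H14N2,-72998.89,-72995.26,NA,2,alpha,-4.585,-0.33499999999999996,Cu=0.257;guest=0.2
Cu(b66)B12N12-Cad,complex,B12N12CuC5H14N2,-72997.27,-72993.71,NA,2,alpha,-4.08,-0.21999999999999997,Cu=0.206;guest=0.198
Cu@B12N12-Cad,complex,B12N12CuC5H14N2,-72986.81,-72982.8,NA,2,alpha,-6.14,-0.45999999999999996,Cu=-0.306;guest=0.354
Al12N12-Cad,complex,Al12N12C5H14N2,-99301.16,-99297.19,NA,1,restricted,-5.8950000000000005,-1.925,NA
CuAl11N12-Cad,complex,CuAl11N12C5H14N2,-137510.87,-137507.22,NA,2,alpha,-3.96,-2,Cu=0.279;guest=0.246
Al12N11Cu-Cad,complex,Al12N11CuC5H14N2,-142624.56,-142620.97,NA,2,alpha,-4.42,-2.0999999999999996,Cu=-0.336;guest=0.289
Cu(b64)Al12N12-Cad,complex,Al12N12CuC5H14N2,-144121.07,-144117.47,NA,2,alpha,-3.37,-1.79,Cu=0.137;guest=0.237
Cu(b66)Al12N12-Cad,complex,Al12N12CuC5H14N2,-144119.75,-144116.2,NA,2,alpha,-3.2649999999999997,-1.835,Cu=0.146;guest=0.243
Cu@Al12N12-Cad,complex,Al12N12CuC5H14N2,-144111.9,-144107.9,NA,2,beta,-5.574999999999999,-2.525,Cu=0.156;guest=0.330
Cu(b64)B12N12-NO,complex,B12N12CuNO,-71988.75,NA,NA,2,alpha,-4.34,-2.4000000000000004,NA
Cu(b64)B12N12-H2O,complex,B12N12CuH2O,-72933.29,NA,NA,2,alpha,-4.915,-0.8250000000000002,NA
Cu(b64)B12N12-H2,complex,B12N12CuH2,-70889.55,NA,NA,2,alpha,-4.765000000000001,-0.7349999999999999,NA
Cu(b64)B12N12-H2S,complex,B12N12CuH2S,-81718.1,NA,NA,2,alpha,-4.845000000000001,-0.855,NA
Cu(b64)B12N12-CO,complex,B12N12CuCO,-73938.59,NA,NA,2,alpha,-4.49,-2.01,NA
Cu(b64)B12N12-COCl2,complex,B12N12CuCOCl2,-99458.41,NA,NA,2,beta,-7.005000000000001,-2.055,NA
Cu(b64)B12N12-N2O,complex,B12N12CuN2O,-75868.22,NA,NA,2,alpha,-5.105,-1.6549999999999998,NA
Cu(b64)B12N12-N2,complex,B12N12CuN2,-73837.98,NA,NA,2,alpha,-4.89,-2.1100000000000003,NA
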