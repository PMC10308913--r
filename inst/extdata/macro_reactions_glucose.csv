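species,e1,e2,e3,e4,e5,e6,e7,e8,e9
substrate,-1,-1,-1,-1,-1,-1,-1,-1,-1
salts,0,-0.006,-0.039,0,-0.004,-0.04,-0.043,0,-0.012
atp,0,-0.008,-0.057,0,-0.005,-0.06,-0.064,0,-0.018
co2,-0.361,0.048,0.333,-0.542,-0.751,0.255,0.372,-0.361,-2.166
co_a,-7.26e-7,-8.27e-5,-5.70e-4,-2.26e-6,-5.20e-5,-5.96e-4,-6.37e-4,-6.91e-7,-1.81e-4
ammonium,-0.001,-0.139,-0.956,-0.004,-0.087,-0.999,-1.068,-0.001,-0.304
biomass,0,0.019,0.129,0.001,0.012,0.134,0.144,0,0.041
acetate,0,2.623,0.414,1.089,0,0,0,0,0
succinate,0.723,0,0,0,1.562,0.187,0,0.723,0.663
formate,0,0,0,1.087,0,0,0,0,3.881
proton_c,0,0,1.138,0,2.467,0,0,0,4.806
proton_e,1.327,2.754,0,2.09,0,0,1.003,1.326,0
glycogen,0.096,0,0.002,0.09,0.002,0,0.008,0.096,0.003
ppi,1.27e-5,1.45e-3,1.00e-2,3.96e-5,9.13e-4,1.05e-2,1.12e-2,1.21e-5,3.19e-3
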