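# RhoA-Rac1 network kinetic parameters.
# v*: maximal rates (1/s); k*: dimensionless Michaelis/modifier constants;
# gamma*: dimensionless modifier strengths; *tot: abundances (conc. units);
# p: dimensionless total PAK.
vGEFRho: 0.12
kGEFRho: 0.3
vGAPRho: 0.19
kGAPRho: 0.3
vGEFRac: 0.033
kGEFRac: 0.3
vGAPRac: 0.105
kGAPRac: 0.15
vaDIA: 0.4
kaDIA: 0.04
viDIA: 1
kiDIA: 0.02
vaROCK: 0.4
kaROCK: 0.06
viROCK: 1
kiROCK: 0.03
vaPAK: 0.06
kaPAK: 0.6
viPAK: 0.106
kiPAK: 0.005
gammaDIARho: 5
kDIARho: 0.6
gammaPAKRho: 0.02
kPAKRho: 0.09
gammaRhoDIA: 4
kRhoDIA: 0.16
gammaRhoROCK: 4
kRhoROCK: 0.35
gammaDIARac: 5
kDIARac: 0.45
gammaPAKRac: 1.6
kPAKRac: 0.4
gammaROCKRac: 3.5
kROCKRac: 6
gammaRacPAK: 6
kRacPAK: 0.35
Rhotot: 25
Ractot: 20
DIAtot: 2
ROCKtot: 2.2
PAKtot: 2
p: 1
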