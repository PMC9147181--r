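MW
LogP
MR
TPSA
HBA1
HBA2
HBD
NumF
nAtoms
nHeavy
nH
nB
nC
nN
nO
nSi
nP
nS
nCl
nSe
nBr
nI
nHetero
nHalogen
nBonds
nBondsS
nBondsD
nBondsT
nRotatable
FracCSP3
MeanBondOrder
nRings
nRingAtoms
FracRingAtoms
nAromRings
nAliphRings
nHeteroRings
nRing3
nRing4
nRing5
nRing6
nRing7
nRing8plus
MaxRingSize
nDeg1
nDeg2
nDeg3
nDeg4
MeanDegree
MaxDegree
Zagreb1
Zagreb2
GraphDensity
FracTerminal
Wiener
MeanDistance
BalabanJ
Radius
Diameter
MeanEcc
PetitjeanShape
Kappa1
Kappa2
Kappa3
Chi0
Chi1
Chi0v
Chi1v
nPairsD1
nPairsD2
nPairsD3
nPairsD4
nPairsD5
nPairsD6
nPairsD7
nPairsD8
nPairsD9
nPairsD10
FracPairsWithin3
TopoComplexity
ATSm0
ATSm1
ATSm2
ATSm3
ATSm4
ATSm5
ATSm6
ATSm7
ATSe0
ATSe1
ATSe2
ATSe3
ATSe4
ATSe5
ATSe6
ATSe7
ATSr0
ATSr1
ATSr2
ATSr3
ATSr4
ATSr5
ATSr6
ATSr7
ATSp0
ATSp1
ATSp2
ATSp3
ATSp4
ATSp5
ATSp6
ATSp7
ATSv0
ATSv1
ATSv2
ATSv3
ATSv4
ATSv5
ATSv6
ATSv7
MoranM1
MoranM2
MoranM3
MoranM4
MoranM5
MoranM6
MoranM7
MoranM8
MoranE1
MoranE2
MoranE3
MoranE4
MoranE5
MoranE6
MoranE7
MoranE8
MoranR1
MoranR2
MoranR3
MoranR4
MoranR5
MoranR6
MoranR7
MoranR8
MoranP1
MoranP2
MoranP3
MoranP4
MoranP5
MoranP6
MoranP7
MoranP8
MoranV1
MoranV2
MoranV3
MoranV4
MoranV5
MoranV6
MoranV7
MoranV8
GearyM1
GearyM2
GearyM3
GearyM4
GearyM5
GearyM6
GearyM7
GearyM8
GearyE1
GearyE2
GearyE3
GearyE4
GearyE5
GearyE6
GearyE7
GearyE8
GearyR1
GearyR2
GearyR3
GearyR4
GearyR5
GearyR6
GearyR7
GearyR8
GearyP1
GearyP2
GearyP3
GearyP4
GearyP5
GearyP6
GearyP7
GearyP8
GearyV1
GearyV2
GearyV3
GearyV4
GearyV5
GearyV6
GearyV7
GearyV8
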