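# 30-molecule fixture set: enophile classes plus common (hetero)aromatics
C=C ethylene
C#C acetylene
CC=CC 2-butene
C=CC=C butadiene
C=CC=CC=C hexatriene
c1ccccc1 benzene
c1ccc2ccccc2c1 naphthalene
c1ccncc1 pyridine
c1cc[nH]c1 pyrrole
c1ccoc1 furan
c1ccsc1 thiophene
Cn1cccc1 N-methylpyrrole
O=Cc1ccccc1 benzaldehyde
CC(C)=O acetone
COC(=O)C=C methyl_acrylate
C=CC#N acrylonitrile
O=C1N(C)C(=O)C=C1 N-methylmaleimide
O=C1OC(=O)C=C1 maleic_anhydride
O=C1N(c2ccccc2)C(=O)N=N1 PTAD
O=Nc1ccc(Cl)cc1 4-chloronitrosobenzene
O=NC(C)(C)C 2-methyl-2-nitrosopropane
CCOC(=O)N=NC(=O)OCC DEAD
C1=CC=CC=CC1 cycloheptatriene
C=Cc1ccccc1 styrene
CC#CC 2-butyne
COC(=O)C#CC(=O)OC DMAD
Oc1ccccc1 phenol
Nc1ccc(N=O)cc1 4-nitrosoaniline
Clc1ccccc1Cl 1,2-dichlorobenzene
CC(=O)Nc1ccccc1 acetanilide
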