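name,smiles,class,fragment,external_lubo,unit
ethylene,C=C,alkene,C=C,NA,beta
propene,CC=C,alkene,C=C,NA,beta
2-methyl-2-butene,CC=C(C)C,alkene,C=C,NA,beta
styrene,C=Cc1ccccc1,alkene,C=C,NA,beta
4-methylstyrene,C=Cc1ccc(C)cc1,alkene,C=C,NA,beta
methyl acrylate,COC(=O)C=C,alkene,C=C,NA,beta
acrylonitrile,C=CC#N,alkene,C=C,NA,beta
acrolein,O=CC=C,alkene,C=C,NA,beta
methyl vinyl ketone,CC(=O)C=C,alkene,C=C,NA,beta
N-methylmaleimide,O=C1N(C)C(=O)C=C1,alkene,C=C,NA,beta
maleic anhydride,O=C1OC(=O)C=C1,alkene,C=C,NA,beta
cyclohexene,C1=CCCCC1,alkene,C=C,NA,beta
methyl vinyl ether,COC=C,alkene,C=C,NA,beta
2-butyne,CC#CC,alkyne,C#C,NA,beta
1-hexyne,CCCCC#C,alkyne,C#C,NA,beta
phenylacetylene,C#Cc1ccccc1,alkyne,C#C,NA,beta
diphenylacetylene,c1ccccc1C#Cc1ccccc1,alkyne,C#C,NA,beta
methyl propiolate,COC(=O)C#C,alkyne,C#C,NA,beta
dimethyl acetylenedicarboxylate,COC(=O)C#CC(=O)OC,alkyne,C#C,NA,beta
formaldehyde,C=O,carbonyl,C=O,NA,beta
acetaldehyde,CC=O,carbonyl,C=O,NA,beta
acetone,CC(C)=O,carbonyl,C=O,NA,beta
butanone,CCC(C)=O,carbonyl,C=O,NA,beta
benzaldehyde,O=Cc1ccccc1,carbonyl,C=O,NA,beta
acetophenone,CC(=O)c1ccccc1,carbonyl,C=O,NA,beta
benzophenone,c1ccccc1C(=O)c1ccccc1,carbonyl,C=O,NA,beta
methyl acetate,COC(C)=O,carbonyl,C=O,NA,beta
nitrosobenzene,O=Nc1ccccc1,nitroso,N=O,NA,beta
2-nitrosotoluene,O=Nc1ccccc1C,nitroso,N=O,NA,beta
4-nitrosotoluene,O=Nc1ccc(C)cc1,nitroso,N=O,NA,beta
4-chloronitrosobenzene,O=Nc1ccc(Cl)cc1,nitroso,N=O,NA,beta
4-methoxynitrosobenzene,O=Nc1ccc(OC)cc1,nitroso,N=O,NA,beta
methyl 4-nitrosobenzoate,O=Nc1ccc(C(=O)OC)cc1,nitroso,N=O,NA,beta
2-methyl-2-nitrosopropane,O=NC(C)(C)C,nitroso,N=O,NA,beta
nitrosomethane,O=NC,nitroso,N=O,NA,beta
4-phenyl-1-2-4-triazoline-3-5-dione,O=C1N(c2ccccc2)C(=O)N=N1,azo,N=N,NA,beta
4-methyl-1-2-4-triazoline-3-5-dione,O=C1N(C)C(=O)N=N1,azo,N=N,NA,beta
diethyl azodicarboxylate,CCOC(=O)N=NC(=O)OCC,azo,N=N,NA,beta
dimethyl azodicarboxylate,COC(=O)N=NC(=O)OC,azo,N=N,NA,beta
azobenzene,c1ccccc1N=Nc1ccccc1,azo,N=N,NA,beta
benzyne,C1#CC=CC=C1,aryne,C#C,0.10,beta
4-5-difluorobenzyne,C1#CC=C(F)C(F)=C1,aryne,C#C,0.12,beta
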