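id,smiles,component_class,amine_count,molar_mass
MC3,CCCCCC/C=C\C/C=C\CCCCCCCC(CCCCCC/C=C\C/C=C\CCCCC)OC(=O)CCN(C)C,ionizable,1,642.1
SM-102,CCCCCCCCCCCOC(=O)CCCCCN(CCO)CCCCCCCC(=O)OC(CCCCCCCC)CCCCCCCC,ionizable,1,710.2
ALC-0315,CCCCCCCCC(CCCCCC)C(=O)OCCCCCCN(CCCCO)CCCCCCOC(=O)C(CCCCCC)CCCCCCCC,ionizable,1,766.3
C12-200,CCCCCCCCCCCCOCC(O)CN(CC(O)COCCCCCCCCCCCC)CCN1CCN(CC(O)COCCCCCCCCCCCC)CC1,ionizable,3,862.4
CKK-E12,CCCCCCCCCCC(O)CN(CC(O)CCCCCCCCCC)CCCCC1NC(=O)C(CCCCN(CC(O)CCCCCCCCCC)CC(O)CCCCCCCCCC)NC1=O,ionizable,2,910.5
DODAP,CCCCCCCC/C=C\CCCCCCCC(=O)OCC(CN(C)C)OC(=O)CCCCCCC/C=C\CCCCCCCC,ionizable,1,648.1
DODMA,CCCCCCCC/C=C\CCCCCCCCOCC(CN(C)C)OCCCCCCCC/C=C\CCCCCCCC,ionizable,1,620.1
DOPE,CCCCCCCC/C=C\CCCCCCCC(=O)OCC(COP(=O)(O)OCCN)OC(=O)CCCCCCC/C=C\CCCCCCCC,helper,,744.0
DSPC,CCCCCCCCCCCCCCCCCC(=O)OCC(COP(=O)([O-])OCC[N+](C)(C)C)OC(=O)CCCCCCCCCCCCCCCCC,helper,,790.1
CHOL,CC(C)CCCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C,sterol,,386.7
B-SITO,CCC(CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C)C(C)C,sterol,,414.7
DC-CHOL,CN(C)CCNC(=O)OC1CCC2(C)C(=CC3C4CCC(C(C)CCCC(C)C)C4(C)CCC23)C1,sterol,,500.8
C14-PEG,CCCCCCCCCCCCCC(=O)OCCOCCOCCOCCOCCOCCOCCOCCOC,peg,,594.8
C18-PEG,CCCCCCCCCCCCCCCCCC(=O)OCCOCCOCCOCCOCCOCCOCCOCCOC,peg,,650.9
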