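pbae_id,repeat_unit_smiles,branch_smiles,repeat_unit_mw
PBAE-1,CCCCCCN(CCO)CCC(=O)OCCCCOC(=O)CC,NCCN(CCN)CCN,373.5
PBAE-2,CCCCCCCCN(CCO)CCC(=O)OCCCCCCOC(=O)CC,NCCNCCNCCN,429.6
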