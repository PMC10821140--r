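pair,generated,reference,tanimoto,qed,sascore,logp
1,COc1ccc(NC(=O)N2CCN(C(=O)C3CCCCC3)CC2)cc1,COc1ccc(NC(=O)N2CCN(C(=O)C3CCCC3)CC2)cc1,0.958,0.916,1.839,2.952
2,Cc1nc2cc3c(cc2n1CC(=O)NC1CCCCC1)OCCO3,Cc1nc2cc3c(cc2n1CC(=O)NC1CCCC1)OCCO3,0.957,0.940,2.318,2.565
3,Cn1ccc(C(=O)Nc2cc(F)ccc2N2CCCC2)cc1=O,Cn1ccc(C(=O)Nc2cc(F)ccc2N2CCCCC2)cc1=O,0.957,0.941,2.184,2.377
4,Cc1cc(CN(C)C(=O)Nc2ccccc2N2CCCC2)no1,Cc1cc(CN(C)C(=O)Nc2ccccc2N2CCCCC2)no1,0.956,0.950,2.102,3.247
5,COc1ccccc1-c1noc(C(=O)N2CCCC2)c1N,COc1ccccc1-c1noc(C(=O)N2CCCCC2)c1N,0.952,0.935,2.284,2.168
6,CC(CC#N)N(C)C(=O)Nc1ccccc1N1CCCC1,CC(CC#N)N(C)C(=O)Nc1ccccc1N1CCCCC1,0.952,0.925,2.685,3.053
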