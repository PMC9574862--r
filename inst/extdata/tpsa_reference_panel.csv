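name,smiles,tpsa_no,tpsa_sp,nc,phi_rdkit
paracetamol,CC(=O)Nc1ccc(O)cc1,49.33,49.33,8,2.108157
aspirin,CC(=O)Oc1ccccc1C(=O)O,63.60,63.60,9,2.639162
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,61.82,61.82,8,1.602259
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,37.30,37.30,13,3.893145
naproxen,COc1ccc2cc(ccc2c1)C(C)C(=O)O,46.53,46.53,14,3.001306
diclofenac,OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl,49.33,49.33,14,4.298278
atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1,84.58,84.58,14,6.316768
metoprolol,COCCc1ccc(OCC(O)CNC(C)C)cc1,50.72,50.72,15,7.480997
propranolol,CC(C)NCC(O)COc1cccc2ccccc12,41.49,41.49,16,4.769932
warfarin,CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O,67.51,67.51,19,3.977030
diazepam,CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1,32.67,32.67,16,3.283253
morphine,CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5,52.93,52.93,17,2.081651
codeine,COc1ccc2CC3C4C=CC(O)C5Oc1c2C45CCN3C,41.93,41.93,18,2.393174
quinine,COc1ccc2nccc(C(O)C3CC4CCN3CC4C=C)c2c1,45.59,45.59,20,4.024010
theophylline,Cn1c2[nH]cnc2c(=O)n(C)c1=O,72.68,72.68,7,1.387017
nicotine,CN1CCCC1c1cccnc1,16.13,16.13,10,2.086141
imatinib,Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(n1)-c1cccnc1,86.28,86.28,29,7.485474
trimethoprim,COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC,105.51,105.51,14,4.318226
metronidazole,Cc1ncc(n1CCO)[N+](=O)[O-],81.19,81.19,6,2.390684
piroxicam,CN1C(=CC(=O)Nc2ccccn2)C(=O)c2ccccc2S1(=O)=O,96.44,104.82,16,3.899541
sulfamethoxazole,Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1,98.22,106.60,10,2.762370
cimetidine,CC1=C(N=CN1)CSCCNC(=NC)NC#N,88.89,114.19,10,5.960448
omeprazole,CC1=CN=C(C(=C1OC)C)CS(=O)C2=NC3=C(N2)C=C(C=C3)OC,77.10,96.31,17,4.526081
fosfomycin,CC1OC1P(=O)(O)O,70.06,79.87,3,1.203303
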