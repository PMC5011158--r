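# Synthetic reconstruction: the external-set structure drawings are not
# machine-readable, so these SMILES were reconstructed from the compound
# names using standard structure databases. Edit freely; they are demo
# input only and no packaged result depends on them.
compound,smiles
Naringenin,O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12
Quercetin,O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
Morin,O=c1c(O)c(-c2ccc(O)cc2O)oc2cc(O)cc(O)c12
Silymarin,O=C1c2c(O)cc(O)cc2OC(c2ccc3OC(c4ccc(O)c(OC)c4)C(CO)Oc3c2)C1O
Epigallocatechin gallate (EGCG),Oc1cc(O)c2c(c1)OC(c1cc(O)c(O)c(O)c1)C(OC(=O)c1cc(O)c(O)c(O)c1)C2
Epicatechin gallate (ECG),Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(OC(=O)c1cc(O)c(O)c(O)c1)C2
Biochenin A,COc1ccc(-c2coc3cc(O)cc(O)c3c2=O)cc1
Hesperidin,COc1ccc(C2CC(=O)c3c(O)cc(OC4OC(COC5OC(C)C(O)C(O)C5O)C(O)C(O)C4O)cc3O2)cc1O
Demethylnobiletin,Oc1c2c(=O)cc(-c3ccc(OC)c(OC)c3)oc2c(OC)c(OC)c1OC
5HHMF,COc1c(OC)c2oc(-c3ccc(OC)c(OC)c3)c(OC)c(=O)c2c(O)c1OC
Nobiletin,COc1ccc(-c2cc(=O)c3c(OC)c(OC)c(OC)c(OC)c3o2)cc1OC
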