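# Synthetic reconstruction: the 23 training-set structure drawings are not
# machine-readable in the source material, so this file ships 23
# representative bioflavonoids as an editable stand-in configuration.
# They are demo input only; no packaged result depends on them.
compound,smiles
Chrysin,O=c1cc(-c2ccccc2)oc2cc(O)cc(O)c12
Apigenin,O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12
Luteolin,O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
Galangin,O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12
Kaempferol,O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12
Quercetin,O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
Myricetin,O=c1c(O)c(-c2cc(O)c(O)c(O)c2)oc2cc(O)cc(O)c12
Fisetin,O=c1c(O)c(-c2ccc(O)c(O)c2)oc2ccc(O)cc12
Morin,O=c1c(O)c(-c2ccc(O)cc2O)oc2cc(O)cc(O)c12
Baicalein,O=c1cc(-c2ccccc2)oc2cc(O)c(O)c(O)c12
Genistein,O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12
Daidzein,O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12
Biochanin A,COc1ccc(-c2coc3cc(O)cc(O)c3c2=O)cc1
Formononetin,COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1
Naringenin,O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12
Hesperetin,COc1ccc(C2CC(=O)c3c(O)cc(O)cc3O2)cc1O
Eriodictyol,O=C1CC(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12
Taxifolin,O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(O)c2)C1O
Catechin,OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1
Epicatechin,OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1
Rutin,O=c1c(OC2OC(COC3OC(C)C(O)C(O)C3O)C(O)C(O)C2O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
Tangeretin,COc1ccc(-c2cc(=O)c3c(OC)c(OC)c(OC)c(OC)c3o2)cc1
Flavone,O=c1cc(-c2ccccc2)oc2ccccc12
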