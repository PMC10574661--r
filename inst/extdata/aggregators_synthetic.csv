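"id","smiles","source"
"agg001","Oc1cc(O)c2c(c1)oc(c(c2=O)O)c1ccc(c(c1)O)O","synthetic_aggregator_standin"
"agg002","Oc1ccc(cc1)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg003","Oc1ccc(c(c1)O)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg004","COc1cc(O)ccc1/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg005","Oc1ccc(c(c1)C)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg006","Oc1ccc(c(c1)Cl)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg007","Oc1ccc(c(c1)Br)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg008","Oc1ccc(c(c1)C(=O)O)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg009","Oc1ccc(c(c1)N)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg010","Oc1ccc(c(c1)F)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg011","CCc1cc(O)ccc1/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg012","CCOc1cc(O)ccc1/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg013","N#Cc1cc(O)ccc1/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg014","Oc1ccc(c(c1)C(=O)C)/C=C/c1cc(O)cc(c1)O","synthetic_aggregator_standin"
"agg015","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg016","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(O)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg017","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(OC)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg018","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(C)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg019","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(Cl)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg020","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(Br)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg021","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(OC)c(c(c2)C(=O)O)O)ccc1O","synthetic_aggregator_standin"
"agg022","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(N)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg023","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(F)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg024","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(CC)c(c(c2)OC)O)ccc1O","synthetic_aggregator_standin"
"agg025","CCOc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(c(c2)OC)O)cc(c1O)OC","synthetic_aggregator_standin"
"agg026","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(OC)c(c(c2)C#N)O)ccc1O","synthetic_aggregator_standin"
"agg027","COc1cc(/C=C/C(=O)CC(=O)/C=C/c2cc(OC)c(c(c2)C(=O)C)O)ccc1O","synthetic_aggregator_standin"
"agg028","Oc1ccc(cc1)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg029","Oc1ccc(c(c1)O)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg030","COc1cc(O)ccc1c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg031","Oc1ccc(c(c1)C)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg032","Oc1ccc(c(c1)Cl)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg033","Oc1ccc(c(c1)Br)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg034","Oc1ccc(c(c1)C(=O)O)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg035","Oc1ccc(c(c1)N)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg036","Oc1ccc(c(c1)F)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg037","CCc1cc(O)ccc1c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg038","CCOc1cc(O)ccc1c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg039","N#Cc1cc(O)ccc1c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg040","Oc1ccc(c(c1)C(=O)C)c1cc(=O)c2c(o1)cc(cc2O)O","synthetic_aggregator_standin"
"agg041","O=c1c(O)c(oc2c1cccc2)c1ccccc1","synthetic_aggregator_standin"
"agg042","Oc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg043","COc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg044","Cc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg045","Clc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg046","Brc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg047","OC(=O)c1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg048","Nc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg049","Fc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
"agg050","CCc1cccc2c1c(=O)c(c(o2)c1ccccc1)O","synthetic_aggregator_standin"
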