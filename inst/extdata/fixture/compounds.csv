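"compound_id","name","smiles","compound_class","source"
"C_001","synthetic_C_001","CC(=O)Oc1ccccc1C(=O)O","flavonoid","synthetic"
"C_002","synthetic_C_002","Oc1ccc(O)cc1","flavonoid","synthetic"
"C_003","synthetic_C_003","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","phosphatidylethanolamine","synthetic"
"C_004","synthetic_C_004","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","phenolic","synthetic"
"C_005","synthetic_C_005","CC(=O)Oc1ccccc1C(=O)O","triacylglycerol","synthetic"
"C_006","synthetic_C_006","OCC1OC(O)C(O)C(O)C1O","diacylglycerol","synthetic"
"C_007","synthetic_C_007","c1ccc2ccccc2c1","anthocyanin","synthetic"
"C_008","synthetic_C_008","c1ccc2ccccc2c1","flavonoid","synthetic"
"C_009","synthetic_C_009","c1ccc2ccccc2c1","anthocyanin","synthetic"
"C_010","synthetic_C_010","CCO","phenolic","synthetic"
"C_011","synthetic_C_011","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","triacylglycerol","synthetic"
"C_012","synthetic_C_012","OCC1OC(O)C(O)C(O)C1O","small_molecule","synthetic"
"C_013","synthetic_C_013","c1ccccc1O","triacylglycerol","synthetic"
"C_014","synthetic_C_014","OCC1OC(O)C(O)C(O)C1O","anthocyanin","synthetic"
"C_015","synthetic_C_015","O=C(O)c1ccccc1","diacylglycerol","synthetic"
"C_016","synthetic_C_016","OCC1OC(O)C(O)C(O)C1O","flavonoid","synthetic"
"C_017","synthetic_C_017","Oc1ccc(O)cc1","small_molecule","synthetic"
"C_018","synthetic_C_018","Oc1ccc(O)cc1","triacylglycerol","synthetic"
"C_019","synthetic_C_019","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","phosphatidylethanolamine","synthetic"
"C_020","synthetic_C_020","O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12","small_molecule","synthetic"
"C_021","synthetic_C_021","CC(C)O","triacylglycerol","synthetic"
"C_022","synthetic_C_022","CC(C)O","small_molecule","synthetic"
"C_023","synthetic_C_023","N","inorganic","synthetic"
"C_024","synthetic_C_024","O=C(O)c1ccccc1","small_molecule","synthetic"
"C_025","synthetic_C_025","CC(=O)Oc1ccccc1C(=O)O","phosphatidylethanolamine","synthetic"
"C_026","synthetic_C_026","c1ccccc1O","small_molecule","synthetic"
"C_027","synthetic_C_027","CC(=O)Oc1ccccc1C(=O)O","small_molecule","synthetic"
"C_028","synthetic_C_028","CCO","anthocyanin","synthetic"
"C_029","synthetic_C_029","O=C(O)c1ccccc1","flavonoid","synthetic"
"C_030","synthetic_C_030","O=C(O)c1ccccc1","small_molecule","synthetic"
"C_031","synthetic_C_031","O=C(O)c1ccccc1","small_molecule","synthetic"
"C_032","synthetic_C_032","CC(=O)Oc1ccccc1C(=O)O","triacylglycerol","synthetic"
"C_033","synthetic_C_033","CC(C)O","diacylglycerol","synthetic"
"C_034","synthetic_C_034","O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12","small_molecule","synthetic"
"C_035","synthetic_C_035","CC(=O)Oc1ccccc1C(=O)O","small_molecule","synthetic"
"C_036","synthetic_C_036","CC(=O)Oc1ccccc1C(=O)O","phenolic","synthetic"
"C_037","synthetic_C_037","c1ccc2ccccc2c1","small_molecule","synthetic"
"C_038","synthetic_C_038","OCC1OC(O)C(O)C(O)C1O","flavonoid","synthetic"
"C_039","synthetic_C_039","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","triacylglycerol","synthetic"
"C_040","synthetic_C_040","O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12","diacylglycerol","synthetic"
"C_041","synthetic_C_041","Oc1ccc(O)cc1","anthocyanin","synthetic"
"C_042","synthetic_C_042","c1ccccc1O","flavonoid","synthetic"
"C_043","synthetic_C_043","CC(=O)Oc1ccccc1C(=O)O","flavonoid","synthetic"
"C_044","synthetic_C_044","c1ccccc1O","phosphatidylethanolamine","synthetic"
"C_045","synthetic_C_045","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","small_molecule","synthetic"
"C_046","synthetic_C_046","Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1","phosphatidylethanolamine","synthetic"
"C_047","synthetic_C_047","[Na+].[Cl-]","inorganic","synthetic"
"C_048","synthetic_C_048","CC(C)O","diacylglycerol","synthetic"
"C_049","synthetic_C_049","O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12","small_molecule","synthetic"
"C_050","synthetic_C_050","c1ccccc1O","small_molecule","synthetic"
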