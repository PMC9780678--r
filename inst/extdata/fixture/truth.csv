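"compound_id","is_active","violated_rule","removed_stage"
"C_001",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity",NA
"C_002",FALSE,"mw",NA
"C_003",FALSE,"H-HT","class"
"C_004",FALSE,"ROA",NA
"C_005",FALSE,"ROA","class"
"C_006",FALSE,"f_char","class"
"C_007",FALSE,"logp",NA
"C_008",FALSE,"n_ring",NA
"C_009",TRUE,NA,NA
"C_010",TRUE,NA,NA
"C_011",FALSE,"Respiratory","class"
"C_012",TRUE,NA,NA
"C_013",FALSE,"n_hd","class"
"C_014",TRUE,NA,NA
"C_015",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity","class"
"C_016",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity",NA
"C_017",TRUE,NA,NA
"C_018",FALSE,"n_hd","class"
"C_019",FALSE,"Carcinogenicity","class"
"C_020",FALSE,"H-HT",NA
"C_021",FALSE,"ROA","class"
"C_022",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity",NA
"C_023",FALSE,"logp","inorganic"
"C_024",TRUE,NA,NA
"C_025",FALSE,"logp","class"
"C_026",FALSE,"n_hd",NA
"C_027",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity",NA
"C_028",FALSE,"n_rot",NA
"C_029",FALSE,"Carcinogenicity",NA
"C_030",FALSE,"hERG",NA
"C_031",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity",NA
"C_032",FALSE,"Ames","class"
"C_033",FALSE,"H-HT","class"
"C_034",FALSE,"H-HT",NA
"C_035",FALSE,"n_rot",NA
"C_036",FALSE,"Respiratory",NA
"C_037",TRUE,NA,NA
"C_038",FALSE,"ROA",NA
"C_039",FALSE,"Genotoxic_Carcinogenicity_Mutagenicity","class"
"C_040",FALSE,"n_ring","class"
"C_041",TRUE,NA,NA
"C_042",TRUE,NA,NA
"C_043",FALSE,"Ames",NA
"C_044",FALSE,"n_ha","class"
"C_045",TRUE,NA,NA
"C_046",FALSE,"Respiratory","class"
"C_047",FALSE,"Carcinogenicity","inorganic"
"C_048",FALSE,"Carcinogenicity","class"
"C_049",FALSE,"ROA",NA
"C_050",FALSE,"ROA",NA
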