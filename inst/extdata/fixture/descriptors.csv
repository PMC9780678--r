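"compound_id","mw","n_ha","n_hd","n_rot","n_ring","f_char","logp"
"C_001",216.159612871706,6,0,9,5,0,4.56829196233302
"C_002",834.70408543013,8,5,2,2,1,3.65983779020607
"C_003",439.84686634969,10,5,5,1,1,1.57373723299243
"C_004",336.153462626971,11,4,4,2,1,1.17898590620607
"C_005",476.11329305917,2,2,1,5,1,3.60920565663837
"C_006",530.558221940883,0,1,10,4,2,3.08299576910213
"C_007",257.969470140524,6,0,1,4,0,7.18513755837921
"C_008",274.100631992333,0,4,4,0,1,2.88225431577303
"C_009",208.438481283374,3,0,8,1,-1,4.26610904894769
"C_010",504.303825125098,11,1,0,1,0,0.986136796697974
"C_011",276.920260144398,8,5,0,3,1,0.936004451848566
"C_012",442.98830117099,3,6,5,3,-1,4.50003739017993
"C_013",433.292228030041,5,12,5,5,0,2.23541714958847
"C_014",211.311198230833,10,6,0,3,0,4.46988114779815
"C_015",478.169711781666,5,0,9,3,1,2.59679589914158
"C_016",496.12992178183,10,3,2,4,0,1.12171010752209
"C_017",236.591503731906,6,3,5,2,-1,1.94651399217546
"C_018",454.575491338037,6,10,10,1,1,1.01687701004557
"C_019",140.805531837977,6,0,0,1,1,3.94557021684013
"C_020",562.403821027838,8,4,0,2,0,1.25914196637459
"C_021",420.234409663826,3,6,3,4,-1,3.68554906211793
"C_022",326.207333295606,2,0,10,4,-1,2.69103070548736
"C_023",236.63119758945,4,0,10,4,-1,-2.63044923904818
"C_024",301.302735414356,0,4,2,2,-1,4.33229520330206
"C_025",145.385971893556,11,6,2,3,-1,5.67986890859902
"C_026",120.708159594797,0,8,4,1,1,4.3983794553671
"C_027",163.214717069641,9,4,0,3,-1,1.07073254291899
"C_028",559.29135336075,5,1,13,1,0,1.88574344459921
"C_029",472.814143439755,4,3,2,1,-1,0.723710712604225
"C_030",176.596012148075,9,3,4,5,0,3.47116082143038
"C_031",237.987426933832,8,2,6,2,-1,2.08941172938794
"C_032",326.625596862286,3,3,9,4,-1,3.2617603296414
"C_033",176.831710124388,4,4,2,5,1,3.12936819097958
"C_034",120.300911157392,2,1,7,3,1,3.59705388494767
"C_035",561.032222746871,1,2,18,1,0,1.39264549920335
"C_036",551.490190587938,8,3,2,2,-1,2.02535942043178
"C_037",300.70054049138,2,6,2,5,0,3.57233068770729
"C_038",565.090984879062,6,0,6,4,-1,2.4366040780209
"C_039",533.059122180566,4,4,5,3,1,2.35936311627738
"C_040",532.30886021629,10,4,0,0,1,4.2524926004
"C_041",577.460418874398,6,0,3,3,-1,0.593994617275894
"C_042",559.106501676142,1,2,8,2,-1,4.62104334435426
"C_043",252.499796082266,9,5,2,5,0,1.59883170071989
"C_044",307.141423532739,20,2,9,5,0,0.770833335397765
"C_045",388.808019426651,7,0,8,2,1,0.24564027194865
"C_046",210.42042452842,3,2,8,2,0,0.213695709453896
"C_047",178.871583500877,0,2,10,4,0,3.85152601902373
"C_048",407.201243950985,10,6,7,1,-1,2.99348799195141
"C_049",166.687591001391,5,2,10,2,0,4.56921444875188
"C_050",252.308151982725,4,3,1,4,-1,1.74801801354624
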