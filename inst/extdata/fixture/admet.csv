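"compound_id","hERG","H-HT","Ames","ROA","Carcinogenicity","Respiratory","Non-Genotoxic_Carcinogenicity","Genotoxic_Carcinogenicity_Mutagenicity"
"C_001",0.219439436970279,0.443890003450215,0.371296880189329,0.191616655634716,0.141512960363179,0.0752033962775022,0.31682812128216,0.966269196653739
"C_002",0.227406192542985,0.346814922997728,0.357896987628192,0.0729874890018254,0.294656990179792,0.0989031034242362,0.229824283868074,0.181460338588804
"C_003",0.184717846484855,0.606228373795748,0.0606829372979701,0.203162931893021,0.0603146474249661,0.192064426196739,0.434359624618664,0.245818970231339
"C_004",0.201223782524467,0.165957957580686,0.0472026549465954,0.947907460685819,0.0243936092406511,0.275701913330704,0.26030529089272,0.28994909263216
"C_005",0.271553276637569,0.166602778751403,0.135380539828911,0.898605410745367,0.210845185499638,0.417097693262622,0.25349823509343,0.416218986492604
"C_006",0.424421704541892,0.0121684975549579,0.0125394694507122,0.0627597282174975,0.07107451220043,0.384334060316905,0.406277543213218,0.12469999848865
"C_007",0.107953956462443,0.0244294111710042,0.177671921625733,0.286712115220726,0.246235172832385,0.376502937851474,0.420923840999603,0.169390123551711
"C_008",0.405036211190745,0.170830630287528,0.193855966581032,0.433372093494982,0.115780638735741,0.432271328251809,0.403351723877713,0.280089567424729
"C_009",0.381826168969274,0.227755519039929,0.0194029120635241,0.214303332259879,0.138999851569533,0.0494691307470202,0.316110553778708,0.174978636838496
"C_010",0.417300761006773,0.09344965047203,0.294875113004819,0.300136344628409,0.203115101326257,0.232458055000752,0.251001892630011,0.04235869852826
"C_011",0.0990177357196808,0.347600017236546,0.278523241858929,0.252283306857571,0.152317949095741,0.713296089433134,0.265358076998964,0.0274934288486838
"C_012",0.338130534971133,0.0553722586203367,0.0261299767903984,0.347885581562296,0.145490670967847,0.353622364094481,0.274946933044121,0.178524262309074
"C_013",0.381019178545102,0.0529779610782862,0.111583617040887,0.378081389889121,0.115304799955338,0.210358892977238,0.0432341107539833,0.0601192121766508
"C_014",0.322905313763767,0.233590499563143,0.124317061472684,0.372647836972028,0.315987593587488,0.0227846225071698,0.435428492128849,0.187827401794493
"C_015",0.227913210708648,0.0609730481542647,0.314399387100711,0.0121276257000864,0.256522937882692,0.266268557952717,0.153053371617571,0.819318695282564
"C_016",0.255053784521297,0.222256597401574,0.347750179162249,0.137493819165975,0.448128721071407,0.2782943546772,0.353168296413496,0.607803247412667
"C_017",0.193234266126528,0.302456744350493,0.189311841046438,0.242865372803062,0.338864024346694,0.359982807990164,0.389885817803443,0.250226255953312
"C_018",0.117859382778406,0.254063766840845,0.172247813874856,0.385760282259434,0.257244663545862,0.350642894264311,0.138338948199525,0.179510852061212
"C_019",0.0944580415450036,0.28180661498569,0.0690261397603899,0.0167967848200351,0.709092301726341,0.0810766851622611,0.0246170878130943,0.38117027846165
"C_020",0.207111495733261,0.736139733437449,0.249179946836084,0.0339280229900032,0.131641667652875,0.0836571310646832,0.0420602670498192,0.400552622433752
"C_021",0.104259613445029,0.21579612522386,0.0460693257674575,0.959388931570575,0.328423976236954,0.253236778341234,0.23089715750888,0.37075529968366
"C_022",0.052376975202933,0.308882231805474,0.0717516942601651,0.0797797824069858,0.363518023360521,0.299557598130777,0.0748565484490245,0.769054877720773
"C_023",0.120707192439586,0.282889602351934,0.0829054705239832,0.0395671064406633,0.134486807687208,0.223440174655989,0.190259062433615,0.0709998235013336
"C_024",0.44891826226376,0.352043940536678,0.290005164220929,0.199638769365847,0.342248708885163,0.196549682356417,0.184760282579809,0.338640932301059
"C_025",0.308998829210177,0.139105666074902,0.137295469650999,0.270788932321593,0.0517794799525291,0.0342140990309417,0.409159647729248,0.406917531313375
"C_026",0.189715588735417,0.266616654181853,0.296007605614141,0.322846512617543,0.157396499523893,0.173665934838355,0.17351143496111,0.0215402702894062
"C_027",0.12832576029934,0.224221534654498,0.292200279161334,0.332581497002393,0.384569905595854,0.150551706803963,0.440700343456119,0.70350760105066
"C_028",0.212664597406983,0.094407244361937,0.222081740070134,0.443724149437621,0.359359741732478,0.148271466018632,0.383010315103456,0.172195721063763
"C_029",0.133449968937784,0.0756081151496619,0.282953823581338,0.372440619980916,0.799936857698485,0.0699286500457674,0.400148147484288,0.130002398854122
"C_030",0.6557801985275,0.193606270262972,0.0520497083943337,0.35043914925307,0.268809512658045,0.368052991293371,0.0722892812360078,0.0222967509925365
"C_031",0.0870219492726028,0.200256908098236,0.0733717241045087,0.157723647598177,0.339863694338128,0.196010173810646,0.343676541885361,0.980680389944464
"C_032",0.075468999510631,0.0180258613917977,0.6106341902446,0.162334026060998,0.336163009228185,0.319092079689726,0.221041403319687,0.34526259476319
"C_033",0.428131508938968,0.677457941938192,0.276371921645477,0.323666228512302,0.382873461255804,0.0990317390952259,0.448878258634359,0.346790179749951
"C_034",0.366965607274324,0.69141230141744,0.267737123379484,0.265251160589978,0.19202156198211,0.156897898893803,0.431143859568983,0.0109303188044578
"C_035",0.304956942554563,0.403842017715797,0.0408462610282004,0.169990792050958,0.236757279997692,0.0547156224120408,0.422332167048007,0.0875418608170003
"C_036",0.210830817008391,0.279952075239271,0.318522609528154,0.201749380612746,0.408780178185552,0.944460034845397,0.295145338783041,0.0829137828480452
"C_037",0.419551717238501,0.395978261549026,0.113030313532799,0.0951553679723292,0.125997908590361,0.0528116073366255,0.262868881542236,0.381752770673484
"C_038",0.253065871717408,0.399666525963694,0.431613430939615,0.823992740949616,0.015772864036262,0.347241998240352,0.175572424381971,0.0823881704173982
"C_039",0.295055694272742,0.381457614582032,0.050538256727159,0.242263567773625,0.448720605382696,0.422487896475941,0.264083511866629,0.610836995113641
"C_040",0.152576200840995,0.328547077290714,0.26460736551322,0.0184055526275188,0.158367475457489,0.0881727133411914,0.101468093274161,0.383257604157552
"C_041",0.285460060024634,0.447281837556511,0.145478578303009,0.398617471922189,0.322125152070075,0.0586466522980481,0.1145405919943,0.082649884512648
"C_042",0.0360588480625302,0.332064245659858,0.198006977550685,0.199008886795491,0.440210658656433,0.178262830963358,0.294922327464446,0.201693329308182
"C_043",0.377649988271296,0.0262806140631437,0.937937755463645,0.267525242557749,0.122762540085241,0.432347121210769,0.203443697467446,0.0427109741233289
"C_044",0.39571029397659,0.201934178741649,0.303403974547982,0.0493470451328903,0.444539772840217,0.325972418226302,0.306329217627645,0.324493843568489
"C_045",0.277288303971291,0.116219496233389,0.219896057797596,0.109963779794052,0.0548194210976362,0.427956152902916,0.088098167758435,0.270253412388265
"C_046",0.120711143659428,0.334382360130549,0.0642726756911725,0.0324510464817286,0.115449294494465,0.936656165439635,0.024791283654049,0.145011721840128
"C_047",0.264058457594365,0.420366666754708,0.179669193746522,0.0997278576903045,0.593320556394756,0.239334272770211,0.232374501181766,0.374571527829394
"C_048",0.389306863341481,0.0129976367950439,0.294999723695219,0.377656893813983,0.664016627287492,0.111117992280051,0.163153916113079,0.286913363123313
"C_049",0.20219515748322,0.311640533516183,0.0478865455463529,0.568134476644918,0.159768692916259,0.0398631154932082,0.0192266516387463,0.203769166972488
"C_050",0.0909076999966055,0.377186969928443,0.201254576202482,0.962133340854198,0.353009811714292,0.0485457319300622,0.116190798385069,0.106607094937935
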