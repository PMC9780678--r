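compound_id	target_id	rank
C_009	P05067	3
C_009	P22303	2
C_009	P42574	1
C_010	P05067	1
C_010	P42574	2
C_010	P22303	21
C_012	P05067	2
C_012	P22303	3
C_012	P42574	1
C_014	P05067	3
C_014	P22303	2
C_014	P42574	1
C_017	P22303	1
C_024	P05067	1
C_024	P22303	3
C_024	P42574	2
C_037	P05067	3
C_037	P22303	2
C_037	P42574	1
C_041	P22303	2
C_041	P42574	1
C_042	P05067	1
C_045	P05067	2
C_045	P42574	1
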