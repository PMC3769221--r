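sample,rs2549782,rs2548538,rs2248374,rs2287988,rs1056893
S0001,GG,TT,AA,GG,CC
S0002,TT,AT,AG,AG,CT
S0003,TT,TT,AA,GG,CC
S0004,TT,AA,GG,AA,TT
S0005,GT,AT,AG,AG,CT
S0006,GT,AT,AG,AG,CT
S0007,GT,AT,AG,AG,CT
S0008,TT,AA,GG,AA,TT
S0009,GG,TT,AA,GG,CC
S0010,TT,AT,AG,AG,CT
S0011,GT,AA,GG,AA,TT
S0012,GT,AT,AG,AG,CT
S0013,GT,AT,AG,AG,CT
S0014,GT,AT,AG,AG,CT
S0015,TT,TT,AA,GG,CC
S0016,GT,AT,AG,AG,CT
S0017,GT,TT,AA,GG,CC
S0018,TT,AT,AG,AG,CT
S0019,GT,AA,GG,AA,TT
S0020,TT,AT,AG,AG,CT
S0021,GT,AT,--,AG,CT
S0022,GT,AA,GG,AA,TT
S0023,GT,AA,GG,AA,TT
S0024,TT,AA,GG,AA,TT
S0025,GT,AT,AG,AG,CT
S0026,GT,TT,AA,GG,CC
S0027,TT,TT,AA,GG,CC
S0028,TT,AT,AG,AG,CT
S0029,GT,AT,AG,AG,CT
S0030,GT,TT,AA,GG,CC
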