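clone_id,S0001,S0002,S0003,S0004,S0005,S0006,S0007,S0008,S0009,S0010,S0011,S0012,S0013,S0014,S0015,S0016,S0017,S0018,S0019,S0020,S0021,S0022,S0023,S0024,S0025,S0026,S0027,S0028,S0029,S0030,S0031,S0032,S0033,S0034,S0035,S0036,S0037,S0038,S0039,S0040
C0001,1,,0,0,0,1,1,0,0,1,1,2,0,0,1,1,0,1,0,0,0,1,0,1,0,1,,0,2,1,1,0,2,1,2,1,0,0,1,0
C0002,1,0,0,2,1,1,1,0,0,0,0,2,0,0,1,2,0,1,0,0,0,1,1,1,0,2,0,0,2,1,0,0,1,1,2,1,1,0,1,0
C0003,1,0,0,1,1,,2,0,0,2,1,1,1,1,,0,0,0,1,0,0,1,0,1,0,1,0,0,2,1,1,0,1,0,0,1,0,0,1,0
C0004,1,0,,2,0,1,0,0,0,2,1,1,0,0,0,1,0,1,0,0,0,1,1,1,0,2,0,0,2,1,1,1,1,1,1,1,,1,1,0
C0005,0,0,0,2,2,0,2,0,0,1,0,2,0,1,1,1,0,0,1,0,0,1,0,1,0,1,0,1,2,1,0,1,1,1,2,1,1,1,1,0
C0006,0,0,0,2,2,0,1,0,0,2,1,1,0,0,0,1,0,0,0,0,0,1,1,1,0,2,1,0,2,0,0,1,1,1,0,1,1,1,1,0
C0007,1,0,0,1,1,0,1,0,1,1,0,1,1,1,2,0,0,1,1,0,0,2,0,1,1,1,1,0,2,0,1,0,1,1,2,1,1,2,0,0
C0008,1,0,1,1,2,0,2,1,1,0,0,1,0,0,2,0,0,1,0,0,,2,1,2,1,2,1,0,2,0,1,0,0,1,2,1,1,2,0,
C0009,0,0,1,0,1,,2,1,0,,0,1,1,0,2,0,1,2,0,0,0,2,,0,0,2,1,0,2,0,1,0,0,1,1,1,2,2,2,0
C0010,0,0,0,0,2,0,1,1,1,1,0,1,0,0,2,1,0,2,1,0,0,2,1,1,0,2,1,0,2,0,1,0,1,1,2,1,2,2,1,0
C0011,1,0,0,1,1,1,2,1,1,1,0,1,0,1,2,0,0,1,0,0,0,2,0,1,1,2,1,,2,0,1,0,0,0,1,1,0,2,1,0
C0012,,0,0,0,2,1,2,1,,0,0,1,1,1,1,0,,1,1,0,0,2,1,0,1,2,0,0,2,0,1,0,1,0,2,1,2,1,1,0
C0013,0,1,0,1,2,0,1,2,2,0,1,1,1,1,1,0,1,1,1,0,0,0,0,0,1,2,0,0,1,0,1,2,1,1,1,1,1,1,1,0
C0014,1,1,0,1,2,0,1,2,1,0,1,1,1,0,2,0,2,1,1,0,1,0,0,1,1,2,1,0,1,0,1,1,,1,1,1,0,1,1,0
C0015,0,1,0,1,2,0,1,2,1,0,1,1,0,0,2,0,0,1,1,,0,1,0,0,0,0,0,0,1,0,1,2,1,1,1,1,0,1,1,0
C0016,0,1,0,1,1,0,1,2,1,0,1,1,0,1,2,0,1,1,1,0,0,0,0,1,0,1,0,0,1,0,1,1,0,0,1,1,1,2,0,1
C0017,1,1,0,1,1,0,1,2,2,0,1,1,1,1,1,0,0,1,2,0,1,1,0,1,,1,0,0,1,0,1,1,1,1,1,0,1,2,1,1
C0018,1,1,0,1,1,0,1,1,2,0,1,1,0,1,2,0,2,1,1,0,1,1,0,1,1,,0,0,1,0,1,2,1,0,1,1,1,2,0,0
C0019,0,1,1,1,0,0,2,1,0,1,1,0,0,1,0,0,1,1,1,1,0,1,2,2,0,0,1,1,0,1,0,0,2,0,0,1,,,0,1
C0020,1,0,1,1,0,1,2,0,0,1,0,0,0,0,0,1,1,1,1,0,0,1,1,0,0,0,1,1,1,0,1,0,2,1,0,0,0,1,0,1
C0021,0,0,0,2,1,1,2,0,0,1,1,1,0,0,,1,0,1,1,1,0,1,1,1,0,0,1,1,1,1,1,1,1,0,0,1,0,,0,1
C0022,1,0,0,2,0,,2,1,0,1,1,1,0,1,0,1,0,1,1,1,0,1,1,2,0,0,0,,1,0,1,1,2,1,0,0,0,0,0,
C0023,0,2,1,2,1,0,1,1,0,0,0,,0,0,0,0,0,1,0,1,0,1,2,1,0,0,0,0,0,1,0,1,1,0,0,0,0,0,0,1
C0024,0,2,0,2,0,1,2,0,0,0,0,0,0,1,0,0,1,1,0,0,0,1,2,1,0,0,0,0,1,0,2,1,2,0,0,0,0,0,0,1
C0025,0,0,0,0,1,1,1,1,0,1,1,2,0,2,0,0,0,0,0,0,0,0,1,0,0,0,2,2,1,1,1,1,2,1,0,0,0,1,1,1
C0026,0,0,0,1,2,1,1,1,0,2,0,2,0,0,0,0,0,0,0,0,0,0,1,1,0,0,1,1,1,0,1,1,1,0,0,0,1,0,2,1
C0027,0,1,0,1,1,1,1,0,0,2,0,1,0,1,0,0,0,0,1,0,0,0,1,2,0,0,1,1,1,0,0,1,2,0,1,0,0,0,1,1
C0028,0,0,0,2,1,0,2,1,0,1,0,1,0,1,0,1,0,0,1,0,0,0,1,0,0,1,1,1,1,1,0,0,2,1,0,0,0,1,2,1
C0029,0,0,0,2,0,2,2,1,0,1,1,1,1,1,0,2,1,0,2,0,0,0,1,2,0,0,2,0,1,0,1,0,2,0,1,0,0,1,2,1
C0030,0,1,0,1,1,0,1,0,0,1,,1,0,1,0,1,,0,1,0,0,0,1,1,0,1,2,2,1,1,1,0,2,0,1,0,1,0,1,1
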