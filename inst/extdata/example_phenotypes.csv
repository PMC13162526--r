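clone_id,location,year,block_id,is_check,score_1,score_2,score_3,score_4,score_5,score_6,plot_mean
C0017,LOC1,2020,LOC1_B01,FALSE,6,6,6,5,6,6,5.83333333333333
C0016,LOC1,2020,LOC1_B01,FALSE,5,5,4,4,4,5,4.5
C0015,LOC1,2020,LOC1_B01,FALSE,5,4,6,5,5,5,5
C0008,LOC1,2020,LOC1_B01,FALSE,6,6,7,7,7,6,6.5
C0029,LOC1,2020,LOC1_B01,FALSE,5,4,5,4,4,4,4.33333333333333
C0025,LOC1,2020,LOC1_B01,FALSE,5,5,5,5,5,5,5
C0011,LOC1,2020,LOC1_B01,FALSE,5,5,6,5,5,5,5.16666666666667
C0022,LOC1,2020,LOC1_B01,FALSE,5,4,5,5,5,5,4.83333333333333
C0021,LOC1,2020,LOC1_B01,FALSE,5,5,4,5,5,4,4.66666666666667
C0013,LOC1,2020,LOC1_B01,FALSE,7,6,7,7,7,6,6.66666666666667
C0006,LOC1,2020,LOC1_B02,FALSE,6,5,6,5,6,5,5.5
C0019,LOC1,2020,LOC1_B02,FALSE,3,3,3,3,3,3,3
C0028,LOC1,2020,LOC1_B02,FALSE,5,4,5,5,5,4,4.66666666666667
C0027,LOC1,2020,LOC1_B02,FALSE,5,4,4,3,3,4,3.83333333333333
C0024,LOC1,2020,LOC1_B02,FALSE,5,5,4,5,4,4,4.5
C0009,LOC1,2020,LOC1_B02,FALSE,7,6,7,7,7,7,6.83333333333333
C0030,LOC1,2020,LOC1_B02,FALSE,3,3,2,3,2,3,2.66666666666667
C0010,LOC1,2020,LOC1_B02,FALSE,4,4,4,4,4,4,4
C0007,LOC1,2020,LOC1_B02,FALSE,4,5,5,5,4,5,4.66666666666667
C0014,LOC1,2020,LOC1_B02,FALSE,5,4,4,6,4,5,4.66666666666667
C0012,LOC1,2020,LOC1_B03,FALSE,4,4,5,5,4,5,4.5
C0026,LOC1,2020,LOC1_B03,FALSE,4,4,4,4,5,4,4.16666666666667
C0003,LOC1,2020,LOC1_B03,FALSE,6,5,5,5,6,5,5.33333333333333
C0020,LOC1,2020,LOC1_B03,FALSE,7,7,6,5,6,6,6.16666666666667
C0023,LOC1,2020,LOC1_B03,FALSE,5,4,5,5,5,4,4.66666666666667
C0018,LOC1,2020,LOC1_B03,FALSE,3,4,4,4,3,4,3.66666666666667
C0005,LOC1,2020,LOC1_B03,FALSE,5,6,4,5,5,5,5
C0004,LOC1,2020,LOC1_B03,FALSE,6,7,6,6,7,8,6.66666666666667
C0001,LOC1,2020,LOC1_B01,TRUE,3,4,5,4,4,5,4.16666666666667
C0002,LOC1,2020,LOC1_B01,TRUE,4,4,4,4,4,4,4
C0001,LOC1,2020,LOC1_B02,TRUE,4,5,4,3,5,4,4.16666666666667
C0002,LOC1,2020,LOC1_B02,TRUE,3,3,4,3,3,3,3.16666666666667
C0001,LOC1,2020,LOC1_B03,TRUE,4,5,5,5,5,5,4.83333333333333
C0002,LOC1,2020,LOC1_B03,TRUE,5,5,4,5,4,5,4.66666666666667
C0023,LOC2,2020,LOC2_B01,FALSE,7,6,6,7,6,6,6.33333333333333
C0021,LOC2,2020,LOC2_B01,FALSE,6,6,6,6,6,6,6
C0007,LOC2,2020,LOC2_B01,FALSE,7,8,7,7,7,7,7.16666666666667
C0018,LOC2,2020,LOC2_B01,FALSE,4,5,4,3,5,4,4.16666666666667
C0020,LOC2,2020,LOC2_B01,FALSE,6,7,7,7,6,6,6.5
C0004,LOC2,2020,LOC2_B01,FALSE,7,8,6,8,7,7,7.16666666666667
C0008,LOC2,2020,LOC2_B01,FALSE,5,5,5,5,5,5,5
C0005,LOC2,2020,LOC2_B01,FALSE,7,7,7,7,7,7,7
C0022,LOC2,2020,LOC2_B01,FALSE,8,8,8,9,8,8,8.16666666666667
C0017,LOC2,2020,LOC2_B01,FALSE,8,7,8,8,8,8,7.83333333333333
C0011,LOC2,2020,LOC2_B02,FALSE,6,5,6,5,5,5,5.33333333333333
C0009,LOC2,2020,LOC2_B02,FALSE,6,7,6,6,7,6,6.33333333333333
C0016,LOC2,2020,LOC2_B02,FALSE,6,7,5,6,7,6,6.16666666666667
C0029,LOC2,2020,LOC2_B02,FALSE,6,6,6,7,6,6,6.16666666666667
C0003,LOC2,2020,LOC2_B02,FALSE,6,7,6,6,6,7,6.33333333333333
C0027,LOC2,2020,LOC2_B02,FALSE,7,7,6,7,6,6,6.5
C0025,LOC2,2020,LOC2_B02,FALSE,7,6,7,6,7,7,6.66666666666667
C0024,LOC2,2020,LOC2_B02,FALSE,6,7,8,6,7,7,6.83333333333333
C0013,LOC2,2020,LOC2_B02,FALSE,7,6,6,6,7,7,6.5
C0014,LOC2,2020,LOC2_B02,FALSE,9,9,9,8,9,8,8.66666666666667
C0030,LOC2,2020,LOC2_B03,FALSE,6,5,6,5,5,5,5.33333333333333
C0006,LOC2,2020,LOC2_B03,FALSE,8,8,7,8,8,8,7.83333333333333
C0015,LOC2,2020,LOC2_B03,FALSE,6,6,6,6,6,6,6
C0010,LOC2,2020,LOC2_B03,FALSE,8,7,7,8,7,7,7.33333333333333
C0026,LOC2,2020,LOC2_B03,FALSE,5,6,6,8,6,5,6
C0019,LOC2,2020,LOC2_B03,FALSE,6,5,4,6,5,6,5.33333333333333
C0012,LOC2,2020,LOC2_B03,FALSE,5,4,5,4,4,5,4.5
C0028,LOC2,2020,LOC2_B03,FALSE,7,7,7,6,8,8,7.16666666666667
C0001,LOC2,2020,LOC2_B01,TRUE,5,6,5,5,5,5,5.16666666666667
C0002,LOC2,2020,LOC2_B01,TRUE,7,7,8,8,9,8,7.83333333333333
C0001,LOC2,2020,LOC2_B02,TRUE,6,6,7,5,6,6,6
C0002,LOC2,2020,LOC2_B02,TRUE,6,6,6,6,8,6,6.33333333333333
C0001,LOC2,2020,LOC2_B03,TRUE,5,6,5,6,7,6,5.83333333333333
C0002,LOC2,2020,LOC2_B03,TRUE,8,7,8,8,7,8,7.66666666666667
C0004,LOC3,2020,LOC3_B01,FALSE,6,7,7,6,6,6,6.33333333333333
C0020,LOC3,2020,LOC3_B01,FALSE,6,6,6,7,6,6,6.16666666666667
C0009,LOC3,2020,LOC3_B01,FALSE,5,4,4,4,5,5,4.5
C0024,LOC3,2020,LOC3_B01,FALSE,7,7,7,7,8,7,7.16666666666667
C0029,LOC3,2020,LOC3_B01,FALSE,5,4,5,5,4,5,4.66666666666667
C0005,LOC3,2020,LOC3_B01,FALSE,7,7,7,8,7,8,7.33333333333333
C0014,LOC3,2020,LOC3_B01,FALSE,8,9,9,8,7,8,8.16666666666667
C0008,LOC3,2020,LOC3_B01,FALSE,7,7,7,7,7,6,6.83333333333333
C0026,LOC3,2020,LOC3_B01,FALSE,5,6,7,5,6,5,5.66666666666667
C0027,LOC3,2020,LOC3_B01,FALSE,6,6,6,6,6,7,6.16666666666667
C0022,LOC3,2020,LOC3_B02,FALSE,7,7,7,7,7,7,7
C0030,LOC3,2020,LOC3_B02,FALSE,6,6,6,5,6,6,5.83333333333333
C0013,LOC3,2020,LOC3_B02,FALSE,7,7,7,7,7,6,6.83333333333333
C0017,LOC3,2020,LOC3_B02,FALSE,6,7,8,7,7,7,7
C0011,LOC3,2020,LOC3_B02,FALSE,5,4,4,4,4,5,4.33333333333333
C0003,LOC3,2020,LOC3_B02,FALSE,6,6,6,6,6,6,6
C0012,LOC3,2020,LOC3_B02,FALSE,5,6,6,5,6,5,5.5
C0007,LOC3,2020,LOC3_B02,FALSE,6,5,6,7,6,5,5.83333333333333
C0010,LOC3,2020,LOC3_B02,FALSE,7,7,7,7,7,7,7
C0019,LOC3,2020,LOC3_B02,FALSE,7,7,8,7,8,7,7.33333333333333
C0025,LOC3,2020,LOC3_B03,FALSE,7,7,8,8,8,7,7.5
C0023,LOC3,2020,LOC3_B03,FALSE,6,6,6,7,7,7,6.5
C0016,LOC3,2020,LOC3_B03,FALSE,8,7,7,7,7,7,7.16666666666667
C0015,LOC3,2020,LOC3_B03,FALSE,6,6,6,6,6,6,6
C0028,LOC3,2020,LOC3_B03,FALSE,7,8,7,8,8,7,7.5
C0021,LOC3,2020,LOC3_B03,FALSE,7,7,7,6,6,7,6.66666666666667
C0018,LOC3,2020,LOC3_B03,FALSE,4,6,5,6,6,5,5.33333333333333
C0006,LOC3,2020,LOC3_B03,FALSE,7,7,7,7,7,7,7
C0001,LOC3,2020,LOC3_B01,TRUE,6,6,6,6,5,6,5.83333333333333
C0002,LOC3,2020,LOC3_B01,TRUE,7,6,6,7,7,7,6.66666666666667
C0001,LOC3,2020,LOC3_B02,TRUE,6,6,5,6,5,6,5.66666666666667
C0002,LOC3,2020,LOC3_B02,TRUE,7,8,8,7,6,7,7.16666666666667
C0001,LOC3,2020,LOC3_B03,TRUE,7,7,6,6,6,6,6.33333333333333
C0002,LOC3,2020,LOC3_B03,TRUE,8,7,7,7,8,6,7.16666666666667
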