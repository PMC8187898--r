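sample_id,group,drug,A_1,A_2,B_1,B_2,C_1,C_2,DRB1_1,DRB1_2
OXC000001,case,OXC,HLA-A*00:00,HLA-A*11:01,HLA-B*15:02,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*15:01,HLA-DRB1*09:01
OXC000002,case,OXC,HLA-A*11:01,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*07:02,HLA-DRB1*00:00,HLA-DRB1*09:01
OXC000003,case,OXC,HLA-A*30:01,HLA-A*33:03,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*03:01
OXC000004,case,OXC,HLA-A*02:01,HLA-A*33:03,HLA-B*00:00,HLA-B*00:00,,,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000005,case,OXC,HLA-A*00:00,HLA-A*11:01,HLA-B*15:02,HLA-B*00:00,HLA-C*01:02,HLA-C*08:01,HLA-DRB1*00:00,HLA-DRB1*12:02
OXC000006,case,OXC,HLA-A*24:02,HLA-A*11:01,HLA-B*46:01,HLA-B*58:01,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000007,case,OXC,HLA-A*00:00,HLA-A*11:01,HLA-B*38:02,HLA-B*38:02,HLA-C*03:04,HLA-C*00:00,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000008,case,OXC,HLA-A*02:01,HLA-A*00:00,HLA-B*00:00,HLA-B*46:01,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000009,case,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*40:01,HLA-B*00:00,HLA-C*00:00,HLA-C*12:03,HLA-DRB1*00:00,HLA-DRB1*03:01
OXC000010,case,OXC,HLA-A*11:01,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*12:03,HLA-C*03:04,HLA-DRB1*00:00,HLA-DRB1*15:01
OXC000011,case,OXC,HLA-A*02:07,HLA-A*33:03,HLA-B*00:00,HLA-B*46:01,HLA-C*01:02,HLA-C*00:00,HLA-DRB1*12:02,HLA-DRB1*09:01
OXC000012,case,OXC,HLA-A*02:01,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*01:02,HLA-DRB1*15:01,HLA-DRB1*15:01
OXC000013,case,OXC,HLA-A*02:01,HLA-A*11:01,HLA-B*00:00,HLA-B*13:01,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000014,case,OXC,HLA-A*24:02,HLA-A*00:00,HLA-B*00:00,HLA-B*13:01,HLA-C*07:02,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*03:01
OXC000015,case,OXC,HLA-A*02:07,HLA-A*33:03,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*07:02,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000016,case,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*13:01,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*15:01,HLA-DRB1*00:00
OXC000017,case,OXC,HLA-A*11:01,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*01:02,HLA-C*00:00,HLA-DRB1*09:01,HLA-DRB1*09:01
OXC000018,case,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*01:02,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000019,case,OXC,HLA-A*02:01,HLA-A*00:00,HLA-B*13:01,HLA-B*15:02,HLA-C*00:00,HLA-C*07:02,HLA-DRB1*15:01,HLA-DRB1*00:00
OXC000020,case,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*58:01,HLA-B*46:01,HLA-C*07:02,HLA-C*08:01,HLA-DRB1*15:01,HLA-DRB1*09:01
OXC000021,control,OXC,HLA-A*00:00,HLA-A*31:01,HLA-B*00:00,HLA-B*58:01,HLA-C*00:00,HLA-C*07:02,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000022,control,OXC,HLA-A*00:00,HLA-A*24:02,HLA-B*58:01,HLA-B*00:00,HLA-C*12:03,HLA-C*01:02,HLA-DRB1*15:01,HLA-DRB1*12:02
OXC000023,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*15:02,HLA-B*00:00,HLA-C*01:02,HLA-C*00:00,HLA-DRB1*15:01,HLA-DRB1*15:01
OXC000024,control,OXC,HLA-A*02:07,HLA-A*11:01,HLA-B*15:02,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000025,control,OXC,HLA-A*00:00,HLA-A*02:01,HLA-B*00:00,HLA-B*15:02,HLA-C*03:04,HLA-C*03:04,HLA-DRB1*00:00,HLA-DRB1*09:01
OXC000026,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*12:02,HLA-DRB1*15:01
OXC000027,control,OXC,HLA-A*00:00,HLA-A*33:03,,,HLA-C*00:00,HLA-C*08:01,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000028,control,OXC,HLA-A*00:00,HLA-A*33:03,HLA-B*00:00,HLA-B*00:00,HLA-C*12:03,HLA-C*00:00,HLA-DRB1*09:01,HLA-DRB1*12:02
OXC000029,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*40:01,HLA-B*00:00,HLA-C*00:00,HLA-C*07:02,HLA-DRB1*00:00,HLA-DRB1*09:01
OXC000030,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*15:02,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*12:02,HLA-DRB1*12:02
OXC000031,control,OXC,HLA-A*33:03,HLA-A*00:00,HLA-B*00:00,HLA-B*15:02,HLA-C*00:00,HLA-C*03:04,HLA-DRB1*00:00,HLA-DRB1*12:02
OXC000032,control,OXC,HLA-A*02:01,HLA-A*00:00,HLA-B*00:00,HLA-B*13:01,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*12:02
OXC000033,control,OXC,HLA-A*11:01,HLA-A*00:00,HLA-B*46:01,HLA-B*00:00,HLA-C*03:04,HLA-C*01:02,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000034,control,OXC,HLA-A*11:01,HLA-A*11:01,HLA-B*00:00,HLA-B*46:01,HLA-C*00:00,HLA-C*08:01,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000035,control,OXC,HLA-A*00:00,HLA-A*11:01,HLA-B*58:01,HLA-B*00:00,HLA-C*00:00,HLA-C*03:04,HLA-DRB1*12:02,HLA-DRB1*12:02
OXC000036,control,OXC,HLA-A*11:01,HLA-A*30:01,HLA-B*58:01,HLA-B*40:01,HLA-C*03:04,HLA-C*00:00,HLA-DRB1*12:02,HLA-DRB1*00:00
OXC000037,control,OXC,HLA-A*02:07,HLA-A*24:02,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*01:02,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000038,control,OXC,HLA-A*33:03,HLA-A*02:01,HLA-B*40:01,HLA-B*00:00,HLA-C*08:01,HLA-C*01:02,HLA-DRB1*09:01,HLA-DRB1*09:01
OXC000039,control,OXC,HLA-A*11:01,HLA-A*33:03,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,,
OXC000040,control,OXC,HLA-A*00:00,HLA-A*02:01,HLA-B*00:00,HLA-B*46:01,HLA-C*00:00,HLA-C*08:01,HLA-DRB1*12:02,HLA-DRB1*15:01
OXC000041,control,OXC,HLA-A*11:01,HLA-A*00:00,HLA-B*00:00,HLA-B*58:01,HLA-C*03:04,HLA-C*00:00,,
OXC000042,control,OXC,HLA-A*11:01,HLA-A*11:01,,,HLA-C*01:02,HLA-C*00:00,HLA-DRB1*15:01,HLA-DRB1*03:01
OXC000043,control,OXC,,,HLA-B*00:00,HLA-B*00:00,HLA-C*08:01,HLA-C*00:00,HLA-DRB1*12:02,HLA-DRB1*00:00
OXC000044,control,OXC,HLA-A*02:07,HLA-A*24:02,HLA-B*13:01,HLA-B*00:00,HLA-C*00:00,HLA-C*07:02,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000045,control,OXC,,,HLA-B*00:00,HLA-B*00:00,HLA-C*03:04,HLA-C*01:02,HLA-DRB1*04:03,HLA-DRB1*12:02
OXC000046,control,OXC,HLA-A*33:03,HLA-A*33:03,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*03:01,HLA-DRB1*00:00
OXC000047,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*46:01,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000048,control,OXC,HLA-A*02:01,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*03:04,HLA-C*07:02,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000049,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*13:01,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*12:02,HLA-DRB1*00:00
OXC000050,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*40:01,HLA-B*00:00,HLA-C*03:04,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000051,control,OXC,HLA-A*33:03,HLA-A*00:00,HLA-B*58:01,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000052,control,OXC,HLA-A*31:01,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*03:04,HLA-C*12:03,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000053,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*58:01,HLA-B*00:00,HLA-C*00:00,HLA-C*03:04,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000054,control,OXC,HLA-A*02:01,HLA-A*00:00,HLA-B*46:01,HLA-B*46:01,HLA-C*07:02,HLA-C*01:02,HLA-DRB1*03:01,HLA-DRB1*03:01
OXC000055,control,OXC,HLA-A*02:07,HLA-A*00:00,HLA-B*00:00,HLA-B*00:00,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*09:01
OXC000056,control,OXC,HLA-A*11:01,HLA-A*00:00,HLA-B*00:00,HLA-B*46:01,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*00:00,HLA-DRB1*00:00
OXC000057,control,OXC,HLA-A*00:00,HLA-A*11:01,HLA-B*00:00,HLA-B*35:01,HLA-C*07:02,HLA-C*00:00,HLA-DRB1*09:01,HLA-DRB1*12:02
OXC000058,control,OXC,HLA-A*00:00,HLA-A*02:07,HLA-B*15:02,HLA-B*00:00,HLA-C*07:02,HLA-C*12:03,HLA-DRB1*09:01,HLA-DRB1*00:00
OXC000059,control,OXC,HLA-A*33:03,HLA-A*00:00,HLA-B*40:01,HLA-B*40:01,HLA-C*03:04,HLA-C*08:01,HLA-DRB1*00:00,HLA-DRB1*09:01
OXC000060,control,OXC,HLA-A*00:00,HLA-A*00:00,HLA-B*00:00,HLA-B*46:01,HLA-C*00:00,HLA-C*00:00,HLA-DRB1*15:01,HLA-DRB1*12:02
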