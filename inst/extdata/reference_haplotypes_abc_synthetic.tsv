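rank	A	B	C	frequency
1	A*01:01	B*08:01	C*07:01	0.060
2	A*02:01	B*07:02	C*07:02	0.045
3	A*03:01	B*35:01	C*04:01	0.030
4	A*02:01	B*44:02	C*05:01	0.028
5	A*29:02	B*44:03	C*16:01	0.022
6	A*23:01	B*49:01	C*07:06	0.018
7	A*02:01	B*15:01	C*03:04	0.016
8	A*24:02	B*39:06	C*12:03	0.014
9	A*11:01	B*51:01	C*15:02	0.012
10	A*32:01	B*40:02	C*02:02	0.011
11	A*26:01	B*38:01	C*12:02	0.010
12	A*25:01	B*18:01	C*12:01	0.009
13	A*31:01	B*27:05	C*01:02	0.008
14	A*68:01	B*53:01	C*06:02	0.007
15	A*30:01	B*13:02	C*08:02	0.006
16	A*33:01	B*14:02	C*03:03	0.006
17	A*66:01	B*41:02	C*17:01	0.005
18	A*02:05	B*50:01	C*14:02	0.005
19	A*30:02	B*42:01	C*17:03	0.004
20	A*74:01	B*57:01	C*18:01	0.004
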