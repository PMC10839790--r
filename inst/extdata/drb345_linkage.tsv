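drb1_group	group
1	DR1
10	DR1
8	DR8
15	DR51
16	DR51
3	DR52
11	DR52
12	DR52
13	DR52
14	DR52
4	DR53
7	DR53
9	DR53
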