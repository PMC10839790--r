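arm	chromosome	start	end
6p	chr6	1	59800000
15q	chr15	17000000	101991189
16p	chr16	1	36800000
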