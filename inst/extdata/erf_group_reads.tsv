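group	bark	embryo	latex	leaf	root
I	189	101	108	38	393
II	25	16	99	47	26
III	60	28	5	14	41
IV	21	10	20	3	39
V	3	7	3	1	19
VI	3	4	2	1	19
VI-L	73	25	19	14	52
VII	683	516	737	171	954
VIII	126	150	219	200	137
IX	112	29	14	101	112
X	21	31	3	12	33
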