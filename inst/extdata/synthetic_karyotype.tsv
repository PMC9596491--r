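chromosome	area	scaffold	scaffold_bp
chr1	356.9	scaffold_1	3.55e+08
chr2	313.7	scaffold_2	3.1e+08
chr3	270.6	scaffold_3	2.7e+08
chr4	252.8	scaffold_4	2.5e+08
chr5	226.9	scaffold_5	2.29e+08
chr6	204.6	scaffold_6	2.04e+08
X	54.3	scaffold_7	1.11e+08
micro1	55.7	scaffold_8	5.5e+07
micro2	45.6	scaffold_9	4.6e+07
micro3	38.7	scaffold_10	4e+07
micro4	34.3	scaffold_11	3.5e+07
micro5	30.7	scaffold_12	3e+07
micro6	26.5	scaffold_13	2.6e+07
micro7	19.7	scaffold_14	2.1e+07
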