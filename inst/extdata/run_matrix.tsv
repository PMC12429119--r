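run	gauge	speed	duration
1	22G	3.8	10
2	22G	1.06	30
3	22G	0.637	50
4	25G	2.04	10
5	25G	0.68	30
6	25G	0.41	50
7	27G	1.04	10
8	27G	0.35	30
9	27G	0.21	50
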