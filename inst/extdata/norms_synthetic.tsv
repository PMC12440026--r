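sex	raw	t
f	0	30
f	1	34
f	2	38
f	3	42
f	4	46
f	5	50
f	6	54
f	7	58
f	8	62
f	9	66
f	10	70
m	0	32
m	1	36
m	2	40
m	3	44
m	4	48
m	5	52
m	6	56
m	7	60
m	8	64
m	9	68
m	10	72
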