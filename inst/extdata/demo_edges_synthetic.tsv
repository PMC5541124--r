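accession_a	accession_b	score
P63102	P61983	0.95
P63102	P62260	0.93
P61983	P62260	0.92
Q9QXQ0	P85972	0.88
Q9QXQ0	Q9Z1P2	0.90
P85972	P60711	0.85
Q9Z1P2	P60711	0.82
P60711	P04692	0.80
P05982	P70619	0.72
B5DFC8	B0BNA7	0.96
B5DFC8	Q9DBZ5	0.94
B0BNA7	Q9DBZ5	0.95
Q9DBZ5	Q9EPH8	0.70
Q9Z1Z3	O55012	0.78
P31399	P29419	0.91
P31399	P11662	0.76
P29419	Q63362	0.74
P11662	Q63362	0.81
P11247	P26151	0.66
P26151	Q9R233	0.62
P63102	P85972	0.35
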