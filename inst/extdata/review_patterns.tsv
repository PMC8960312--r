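dosage_type	initial_labels	final_labels	count	forced_review
loss	P,LP	P,LP	3	0
loss	P,VUS	VUS	6	0
loss	P,VUS	P,VUS	3	0
loss	P,VUS	P,LP,VUS	1	0
loss	LP,VUS	P	1	0
loss	LP,VUS	P,LP,VUS	3	0
loss	LP,VUS	LP,VUS	2	0
loss	P,LP,VUS	P	2	0
loss	P,LP,VUS	P,LP,VUS	7	0
loss	P,LP,VUS	P,VUS	2	0
loss	P,LP,VUS,LB,B	P,LP,VUS	2	0
loss	LB,VUS	VUS	3	0
loss	LB,B,VUS	VUS	1	0
loss	LB,B,VUS	LB,B,VUS	3	0
gain	P,LP	P	4	0
gain	P,LP	P,LP	3	0
gain	P,VUS	P	3	0
gain	P,VUS	VUS	1	0
gain	P,VUS	P,LP,VUS	1	0
gain	P,VUS	P,VUS	1	0
gain	LP,VUS	VUS	3	0
gain	LP,VUS	P	1	0
gain	LP,VUS	P,LP,VUS	1	0
gain	LP,VUS	P,VUS	1	0
gain	LP,VUS	P,LP	1	0
gain	P,LP,VUS	P	1	0
gain	P,LP,VUS	VUS	2	0
gain	P,LP,VUS	P,LP,VUS	5	0
gain	P,LP,VUS	P,VUS	1	0
gain	P,LP,VUS	LP,VUS	2	0
gain	P,LP,VUS,LB,B	VUS	1	0
gain	P,LP,VUS,LB,B	P,LP,VUS	1	0
gain	P,LP,VUS,LB,B	LP,VUS	1	0
gain	LB,VUS	VUS	2	0
gain	LB,VUS	LB,VUS	1	0
gain	B,VUS	B	2	0
gain	B,VUS	B,VUS	1	0
gain	LB,B,VUS	VUS	1	0
gain	LB,B,VUS	LB,B,VUS	1	0
gain	LB,B,VUS	VUS,B	1	0
loss	VUS	P,VUS	1	1
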