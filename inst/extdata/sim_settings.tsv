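label	beta1	beta2	beta3	gamma1	gamma2	gamma3	verified
A1	0	0	0	.	.	.	TRUE
A2	0.01	0.01	0.01	.	.	.	TRUE
A3	0.01	0.01	1	.	.	.	TRUE
A4	0.01	0.01	2	.	.	.	TRUE
A5	0.5	0.5	1	.	.	.	TRUE
A6	0.1	0.1	0	.	.	.	TRUE
A7	0.5	0.5	0	.	.	.	TRUE
A8	1	1	0	.	.	.	TRUE
A9	2	2	0	.	.	.	TRUE
B1	0.01	0.01	0.01	0.01	0.01	0.01	TRUE
B2	0.01	0.01	0.5	0.01	0.01	0.5	TRUE
B3	0.01	0.01	1	0.01	0.01	1	TRUE
B4	.	.	.	.	.	.	FALSE
B5	0.5	0.5	0.01	0.5	0.5	0.01	TRUE
B6	1	1	0.01	1	1	0.01	TRUE
B7	.	.	.	.	.	.	FALSE
B8	1	1	1	1	1	1	TRUE
B9	0.01	0.01	0.5	-0.01	-0.01	-0.5	TRUE
B10	0.01	0.01	1	-0.01	-0.01	-1	TRUE
B11	.	.	.	.	.	.	FALSE
B12	0.5	0	0.01	0	0.5	0.01	TRUE
B13	1	0	0.01	0	1	0.01	TRUE
B14	.	.	.	.	.	.	FALSE
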