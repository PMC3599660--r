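sample_id	group	target	tech_rep	ct_target	ct_u6
a1	A	miR-127	1	23.55	20.06
a1	A	miR-127	2	23.59	19.98
a1	A	miR-127	3	23.5	19.93
a2	A	miR-127	1	23.49	19.88
a2	A	miR-127	2	23.36	19.84
a2	A	miR-127	3	23.55	19.88
a3	A	miR-127	1	23.82	20.19
a3	A	miR-127	2	23.76	20.2
a3	A	miR-127	3	23.93	20.25
b1	B	miR-127	1	25.57	20.59
b1	B	miR-127	2	25.56	20.66
b1	B	miR-127	3	25.54	20.57
b2	B	miR-127	1	25.21	20.41
b2	B	miR-127	2	25.26	20.46
b2	B	miR-127	3	25.22	20.49
b3	B	miR-127	1	25.14	20.08
b3	B	miR-127	2	25.13	20.13
b3	B	miR-127	3	25.1	20.12
a1	A	miR-34b	1	25.04	19.93
a1	A	miR-34b	2	25.07	19.83
a1	A	miR-34b	3	24.9	20.01
a2	A	miR-34b	1	25.04	19.3
a2	A	miR-34b	2	25.11	19.35
a2	A	miR-34b	3	25.14	19.2
a3	A	miR-34b	1	25.04	19.88
a3	A	miR-34b	2	24.99	19.89
a3	A	miR-34b	3	25.02	19.94
b1	B	miR-34b	1	23.76	20.27
b1	B	miR-34b	2	23.59	20.26
b1	B	miR-34b	3	23.94	20.24
b2	B	miR-34b	1	23.64	20.47
b2	B	miR-34b	2	23.77	20.6
b2	B	miR-34b	3	23.77	20.54
b3	B	miR-34b	1	24.01	20.52
b3	B	miR-34b	2	23.98	20.53
b3	B	miR-34b	3	24.04	20.49
a1	A	miR-215	1	25.52	20.44
a1	A	miR-215	2	25.33	20.34
a1	A	miR-215	3	25.49	20.34
a2	A	miR-215	1	25.39	19.53
a2	A	miR-215	2	25.35	19.49
a2	A	miR-215	3	25.53	19.51
a3	A	miR-215	1	25.42	20.29
a3	A	miR-215	2	25.37	20.18
a3	A	miR-215	3	25.4	20.13
b1	B	miR-215	1	23.73	20.04
b1	B	miR-215	2	23.77	19.98
b1	B	miR-215	3	23.65	19.96
b2	B	miR-215	1	23.69	19.77
b2	B	miR-215	2	23.63	19.69
b2	B	miR-215	3	23.5	19.79
b3	B	miR-215	1	23.42	20.44
b3	B	miR-215	2	23.41	20.39
b3	B	miR-215	3	23.28	20.26
a1	A	let-7a	1	25.84	20.23
a1	A	let-7a	2	25.89	20.22
a1	A	let-7a	3	25.89	20.31
a2	A	let-7a	1	25.86	20.53
a2	A	let-7a	2	25.79	20.66
a2	A	let-7a	3	25.97	20.52
a3	A	let-7a	1	25.84	20.39
a3	A	let-7a	2	25.96	20.39
a3	A	let-7a	3	25.86	20.44
b1	B	let-7a	1	22.91	20.03
b1	B	let-7a	2	22.87	19.87
b1	B	let-7a	3	22.98	19.88
b2	B	let-7a	1	22.95	19.93
b2	B	let-7a	2	22.96	19.94
b2	B	let-7a	3	22.87	19.93
b3	B	let-7a	1	23.34	20.09
b3	B	let-7a	2	23.31	20.11
b3	B	let-7a	3	23.22	20.14
a1	A	miR-107	1	24.97	20.32
a1	A	miR-107	2	25.04	20.32
a1	A	miR-107	3	24.94	20.3
a2	A	miR-107	1	25.08	20.1
a2	A	miR-107	2	24.93	20.21
a2	A	miR-107	3	25.07	20.09
a3	A	miR-107	1	24.86	19.71
a3	A	miR-107	2	24.8	19.74
a3	A	miR-107	3	24.88	19.84
b1	B	miR-107	1	24	20.01
b1	B	miR-107	2	24.05	20.24
b1	B	miR-107	3	24.08	20.07
b2	B	miR-107	1	24.15	20.14
b2	B	miR-107	2	24.04	20.03
b2	B	miR-107	3	24.12	20.13
b3	B	miR-107	1	24.08	19.54
b3	B	miR-107	2	23.98	19.42
b3	B	miR-107	3	23.95	19.52
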