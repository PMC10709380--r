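subject	group	central	frontal	occipital	parietal	temporal_left	temporal_right	mean
1	1	-2.23	-3.14	-3.39	-3.11	-2.95	-2.96	-2.96
17	2	0.69	0.66	0.92	0.46	0.53	0.45	0.62
2	1	0.45	0.94	0.46	0.31	0.67	0.44	0.55
18	2	1.59	1.45	1.29	2.31	2.07	1.94	1.78
3	1	-0.01	-0.10	0.57	-0.01	0.02	0.30	0.13
19	2	1.00	0.75	0.34	1.02	0.66	0.77	0.76
4	1	-0.23	0.10	-0.30	-0.32	-0.21	-0.26	-0.20
20	2	0.75	0.83	0.62	0.63	0.59	0.63	0.68
5	1	0.25	0.93	0.31	0.48	0.34	0.39	0.45
21	2	0.21	0.36	1.21	0.66	0.18	0.55	0.53
6	1	0.39	0.44	0.75	0.81	0.58	0.47	0.57
22	2	1.02	1.15	0.43	1.20	0.84	0.96	0.93
7	1	-0.19	-0.60	-0.70	0.03	-0.25	-0.41	-0.35
23	2	1.19	1.75	1.10	1.65	1.49	1.46	1.44
8	1	0.55	1.02	0.21	0.76	0.67	0.50	0.62
24	2	0.47	0.19	0.12	0.77	0.50	0.40	0.41
9	1	0.56	0.47	1.11	0.68	0.72	0.35	0.65
25	2	-0.34	-0.41	-0.40	-0.30	-0.27	-0.23	-0.33
10	1	0.55	0.52	0.28	0.53	0.79	1.06	0.62
26	2	1.11	1.56	1.21	1.69	1.74	1.34	1.44
11	1	0.10	0.02	0.08	-0.27	-0.17	-0.12	-0.06
27	2	0.45	0.02	-0.46	0.29	0.64	0.17	0.19
12	1	0.98	1.31	0.88	1.25	1.19	1.13	1.12
28	2	0.74	0.44	0.84	0.87	0.45	0.53	0.65
13	1	0.50	0.47	0.05	0.77	0.36	0.55	0.45
29	2	0.55	1.80	0.34	1.04	0.98	0.92	0.94
14	1	0.50	-0.08	0.12	0.06	0.40	0.45	0.24
30	2	1.90	1.57	0.96	1.53	1.53	1.68	1.53
15	1	-0.91	-1.19	-0.15	-1.05	-0.53	-0.31	-0.69
31	2	1.74	2.39	0.68	1.62	1.85	1.22	1.58
16	1	0.01	0.63	0.65	0.25	0.32	0.20	0.34
32	2	0.09	0.26	0.19	-0.23	0.00	0.18	0.08
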