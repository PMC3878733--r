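size	hairpin	bulge	internal
1	NA	3.8	NA
2	NA	2.8	1.5
3	5.4	3.2	1.6
4	5.6	3.6	1.7
5	5.7	4	1.8
6	5.4	4.4	2
7	6	4.6	2.2
8	5.5	4.7	2.3
9	6.4	4.8	2.4
10	6.5	4.9	2.5
11	6.6	5	2.6
12	6.7	5.1	2.7
13	6.78	5.18	2.78
14	6.86	5.26	2.86
15	6.94	5.34	2.94
16	7.01	5.41	3.01
17	7.07	5.47	3.07
18	7.13	5.53	3.13
19	7.19	5.59	3.19
20	7.25	5.65	3.25
21	7.3	5.7	3.3
22	7.35	5.75	3.35
23	7.4	5.8	3.4
24	7.44	5.84	3.44
25	7.49	5.89	3.49
26	7.53	5.93	3.53
27	7.57	5.97	3.57
28	7.61	6.01	3.61
29	7.65	6.05	3.65
30	7.68	6.08	3.68
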