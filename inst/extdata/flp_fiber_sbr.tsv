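peak	widefield	slm	confocal
1	2.5	3.2	7.0
2	2.5	8.6	8.6
3	5.3	20.5	36.5
4	1.2	2.7	7.2
5	3.6	9.4	13.4
6	1.3	3.5	29.3
7	1.8	4.7	8.7
8	4.6	11.0	25.5
9	1.3	4.0	40.7
10	1.5	6.2	22.7
11	1.8	3.4	3.8
12	1.7	7.6	11.6
13	2.6	15.6	46.0
14	2.6	9.4	22.7
15	1.4	3.5	11.3
16	2.2	5.4	12.7
17	1.4	2.8	10.2
18	1.2	3.4	25.3
19	2.9	10.8	67.0
20	1.2	2.8	7.9
21	1.0	1.9	8.9
22	1.0	1.7	3.5
23	1.0	1.5	2.8
24	1.3	6.4	26.3
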