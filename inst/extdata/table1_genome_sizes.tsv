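clade	species	species_name	clone	mean_mbp	sem	n
A	S.1	B. plicatilis s.s.	AUBUS001	111.7	3.2	4
A	S.1	B. plicatilis s.s.	AUPEA006	116.7	1.7	4
A	S.1	B. plicatilis s.s.	JPNAG062	114.5	1.5	4
A	S.1	B. plicatilis s.s.	L1	128.8	3.0	5
A	S.1	B. plicatilis s.s.	Tokyo1	123.0	1.8	4
A	S.2	B. manjavacas	HOY2	122.5	1.7	4
A	S.2	B. manjavacas	HOY3	127.1	2.4	4
A	S.2	B. manjavacas	MANL5	124.7	2.4	5
A	S.2	B. manjavacas	ONT5	125.0	2.9	4
A	S.2	B. manjavacas	ONT6	122.2	1.8	4
A	S.2	B. manjavacas	SAL4	124.7	1.6	4
A	S.2	B. manjavacas	SAL5	123.9	3.7	4
A	S.2	B. manjavacas	Russia	113.1	2.5	4
A	S.3	B. 'Nevada'	Littlefishpond2	109.1	1.7	4
A	S.4	B. 'Austria'	Bogoria1	217.6	6.6	6
A	S.4	B. 'Austria'	MNCHU008	407.0	7.4	7
A	S.4	B. 'Austria'	MNCHU024	340.0	2.4	6
A	S.4	B. 'Austria'	Nakuru1	221.5	1.7	4
A	S.4	B. 'Austria'	Nakuru2	216.6	4.1	4
A	S.4	B. 'Austria'	OHJ1	229.5	4.1	4
A	S.4	B. 'Austria'	OHJ4	256.3	9.6	4
B	S.6		Mortlock5	87.7	0.6	4
B	S.7		AUYEN020	95.1	2.5	4
B	S.7		Kordaclaypan56	100.4	0.8	4
B	S.8		Warrionlake37	83.5	1.9	4
B	S.9	B. 'Almenara'	ALM7C29	84.6	1.6	4
B	S.9	B. 'Almenara'	Indianrocks1	75.1	1.6	5
B	S.9	B. 'Almenara'	Lostlake1	71.4	1.4	4
B	S.5	B. 'Tiscar'	SM28	82.4	2.6	4
B	S.10	B. ibericus	SM5	99.1	3.3	5
C	S.11	B. rotundiformis	Adriatic2	55.1	0.3	4
C	S.11	B. rotundiformis	HONSS	58.7	1.7	4
C	S.12		Hawaii	58.8	0.4	4
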