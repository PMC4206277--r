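aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-2.1	-2.217	-1.217	-1.217	-2.267	-1.733	-1.267	-2.55	-1.15	-2.433	-2.117	-1.217	-1.533	-1.217	-1.05	-1.667	-1.683	-2.5	-1.65	-1.583
C	-2.217	-3.333	-1.333	-1.333	-2.383	-1.85	-1.383	-2.667	-1.267	-2.55	-2.233	-1.333	-1.65	-1.333	-1.167	-1.783	-1.8	-2.617	-1.767	-1.7
D	-1.217	-1.333	0.167	0.167	-1.383	-0.85	-1.383	-1.667	-1.267	-1.55	-1.233	-0.333	-0.65	-0.333	-1.167	-0.783	-0.8	-1.617	-0.767	-0.7
E	-1.217	-1.333	0.167	0.167	-1.383	-0.85	-1.383	-1.667	-1.267	-1.55	-1.233	-0.333	-0.65	-0.333	-1.167	-0.783	-0.8	-1.617	-0.767	-0.7
F	-2.267	-2.383	-1.383	-1.383	-2.433	-1.9	-1.433	-2.717	-1.317	-2.6	-2.283	-1.383	-1.7	-1.383	-1.217	-1.833	-1.85	-2.667	-1.817	-1.75
G	-1.733	-1.85	-0.85	-0.85	-1.9	-1.367	-0.9	-2.183	-0.783	-2.067	-1.75	-0.85	-1.167	-0.85	-0.683	-1.3	-1.317	-2.133	-1.283	-1.217
H	-1.267	-1.383	-1.383	-1.383	-1.433	-0.9	0.067	-1.717	0.183	-1.6	-1.283	-0.383	-0.7	-0.383	0.283	-0.833	-0.85	-1.667	-0.817	-0.75
I	-2.55	-2.667	-1.667	-1.667	-2.717	-2.183	-1.717	-3	-1.6	-2.883	-2.567	-1.667	-1.983	-1.667	-1.5	-2.117	-2.133	-2.95	-2.1	-2.033
K	-1.15	-1.267	-1.267	-1.267	-1.317	-0.783	0.183	-1.6	0.3	-1.483	-1.167	-0.267	-0.583	-0.267	0.4	-0.717	-0.733	-1.55	-0.7	-0.633
L	-2.433	-2.55	-1.55	-1.55	-2.6	-2.067	-1.6	-2.883	-1.483	-2.767	-2.45	-1.55	-1.867	-1.55	-1.383	-2	-2.017	-2.833	-1.983	-1.917
M	-2.117	-2.233	-1.233	-1.233	-2.283	-1.75	-1.283	-2.567	-1.167	-2.45	-2.133	-1.233	-1.55	-1.233	-1.067	-1.683	-1.7	-2.517	-1.667	-1.6
N	-1.217	-1.333	-0.333	-0.333	-1.383	-0.85	-0.383	-1.667	-0.267	-1.55	-1.233	-0.333	-0.65	-0.333	-0.167	-0.783	-0.8	-1.617	-0.767	-0.7
P	-1.533	-1.65	-0.65	-0.65	-1.7	-1.167	-0.7	-1.983	-0.583	-1.867	-1.55	-0.65	-0.967	-0.65	-0.483	-1.1	-1.117	-1.933	-1.083	-1.017
Q	-1.217	-1.333	-0.333	-0.333	-1.383	-0.85	-0.383	-1.667	-0.267	-1.55	-1.233	-0.333	-0.65	-0.333	-0.167	-0.783	-0.8	-1.617	-0.767	-0.7
R	-1.05	-1.167	-1.167	-1.167	-1.217	-0.683	0.283	-1.5	0.4	-1.383	-1.067	-0.167	-0.483	-0.167	0.5	-0.617	-0.633	-1.45	-0.6	-0.533
S	-1.667	-1.783	-0.783	-0.783	-1.833	-1.3	-0.833	-2.117	-0.717	-2	-1.683	-0.783	-1.1	-0.783	-0.617	-1.233	-1.25	-2.067	-1.217	-1.15
T	-1.683	-1.8	-0.8	-0.8	-1.85	-1.317	-0.85	-2.133	-0.733	-2.017	-1.7	-0.8	-1.117	-0.8	-0.633	-1.25	-1.267	-2.083	-1.233	-1.167
V	-2.5	-2.617	-1.617	-1.617	-2.667	-2.133	-1.667	-2.95	-1.55	-2.833	-2.517	-1.617	-1.933	-1.617	-1.45	-2.067	-2.083	-2.9	-2.05	-1.983
W	-1.65	-1.767	-0.767	-0.767	-1.817	-1.283	-0.817	-2.1	-0.7	-1.983	-1.667	-0.767	-1.083	-0.767	-0.6	-1.217	-1.233	-2.05	-1.2	-1.133
Y	-1.583	-1.7	-0.7	-0.7	-1.75	-1.217	-0.75	-2.033	-0.633	-1.917	-1.6	-0.7	-1.017	-0.7	-0.533	-1.15	-1.167	-1.983	-1.133	-1.067
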