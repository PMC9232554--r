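activator	repressor	reporter
0.050000000000000003	0.35000000000000003	0.40000000000000002
0.10000000000000001	0.30000000000000004	0.60000000000000009
0.30000000000000004	0.10000000000000001	0.60000000000000009
0.5	0	0.45000000000000001
0.25	0.35000000000000003	0.40000000000000002
0.40000000000000002	0.25	0
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.30000000000000004	0.10000000000000001	0.35000000000000003
0.45000000000000001	0.5	0.050000000000000003
0.40000000000000002	0.20000000000000001	0.40000000000000002
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.30000000000000004	0.35000000000000003	0.30000000000000004
0.25	0.55000000000000004	0.10000000000000001
0.55000000000000004	0.35000000000000003	0.10000000000000001
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.35000000000000003	0.40000000000000002	0.25
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.75	0.20000000000000001	0.050000000000000003
0.30000000000000004	0.050000000000000003	0.45000000000000001
0.60000000000000009	0.30000000000000004	0.10000000000000001
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.10000000000000001	0	0.10000000000000001
0.10000000000000001	0.45000000000000001	0.45000000000000001
0.10000000000000001	0.20000000000000001	0.30000000000000004
0.45000000000000001	0.10000000000000001	0.45000000000000001
0.25	0.25	0.5
0.5	0	0.5
0.40000000000000002	0.40000000000000002	0.20000000000000001
0.30000000000000004	0.35000000000000003	0.35000000000000003
0.5	0.5	0
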