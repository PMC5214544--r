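# Front-row rugby player mass distribution (percent of total body mass,
# per-side for bilateral segments) and principal moments of inertia (kg m^2)
# from DEXA-informed measurements of a 1.84 m, 120.4 kg subject.
segment	mass_pct	bilateral	Ixx	Iyy	Izz
HEAD	4.1	0	0.03328	0.01250	0.03589
JAW	0.6	0	0.04000	0.02000	0.04000
TORSO	22.3	0	1.22530	0.96260	2.18700
CERV1	0.6	0	0.03424	0.13697	0.03424
CERV2	0.8	0	0.03064	0.12254	0.03064
CERV3	0.6	0	0.03335	0.13338	0.03335
CERV4	0.6	0	0.03307	0.13229	0.03307
CERV5	0.6	0	0.03263	0.13051	0.03263
CERV6	0.7	0	0.03151	0.12605	0.03151
CERV7	0.8	0	0.03082	0.12327	0.03082
PELVIS	18.2	0	0.19204	0.16271	0.10816
SCAPULA	3.2	1	0.00124	0.00115	0.00137
CLAV	0.7	1	0.00024	0.00026	0.00004
FEMUR	9.9	1	0.17275	0.04528	0.18217
TIBIA	4.0	1	0.04650	0.00820	0.04650
TALLUS	0.1	1	0.00100	0.00100	0.00100
CALCANEUS	1.3	1	0.00179	0.00499	0.00525
TOES	0.2	1	0.00014	0.00028	0.00139
HUMERUS	3.4	1	0.02410	0.00831	0.02705
ULNA	1.0	1	0.00585	0.00122	0.00635
RADIUS	1.0	1	0.00585	0.00122	0.00635
HAND	0.8	1	0.00175	0.00108	0.00264
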