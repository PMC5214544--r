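# Baseline (healthy male) mass distribution, percent of total body mass.
# Per-side values for bilateral segments (bilateral column = 1).
segment	mass_pct	bilateral
HEAD	5.0	0
JAW	0.6	0
TORSO	26.2	0
CERV1	0.7	0
CERV2	0.9	0
CERV3	0.6	0
CERV4	0.6	0
CERV5	0.6	0
CERV6	0.7	0
CERV7	0.9	0
PELVIS	14.7	0
SCAPULA	3.0	1
CLAV	0.6	1
FEMUR	9.3	1
TIBIA	4.6	1
TALLUS	0.1	1
CALCANEUS	1.6	1
TOES	0.3	1
HUMERUS	2.5	1
ULNA	0.8	1
RADIUS	0.8	1
HAND	0.6	1
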