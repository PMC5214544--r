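# DEFAULT cervical coupling fractions (dimensionless slopes): each driven
# intervertebral rotation = fraction x neck master coordinate. A linear
# distribution assumption, NOT measured level-by-level kinematics;
# overridable in the model config.
level	flexion_fraction	bending_fraction	rotation_fraction
c6	1.00	0.95	0.90
c5	0.95	0.90	0.85
c4	0.90	0.85	0.80
c3	0.85	0.80	0.75
c2	0.80	0.75	0.70
c1	0.70	0.65	0.60
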