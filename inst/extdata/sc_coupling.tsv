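# Approximate population-level shoulder-rhythm coupling knots (deg).
# Smooth description of in vivo bone-pin means over 20-140 deg humeral
# elevation; NOT subject-specific, shipped for interpolation mechanics.
elevation	sc_elevation	sc_protraction	sc_axial
20	4.0	-15.0	0.0
40	6.5	-17.0	2.0
60	9.5	-19.5	5.5
80	13.0	-22.5	10.5
100	17.0	-26.0	17.0
120	21.0	-29.5	24.0
140	24.0	-32.0	30.0
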