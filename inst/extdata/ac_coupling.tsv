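# Approximate linear AC-from-SC coupling coefficients (deg / deg, deg).
channel	sc_channel	slope	intercept
lateral	sc_elevation	0.80	2.0
protraction	sc_protraction	0.50	-3.0
tilt	sc_axial	0.30	-1.0
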