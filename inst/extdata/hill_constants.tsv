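constant	value	description
fl_width	0.45	active force-length bell width (normalized length units)
fp_kpe	4.0	passive force-length exponential shape factor
fp_e0	0.35	passive strain at one normalized force
fv_af	0.25	force-velocity concentric curvature (Hill a/F0)
fv_flen	1.4	eccentric force plateau (normalized)
fv_gamma_ecc	0.2	eccentric curvature (normalized velocity scale)
vmax_norm	10	maximum shortening velocity (optimal fiber lengths / s)
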