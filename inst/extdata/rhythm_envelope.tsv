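# Synthetic +/-2 SD reference envelopes for SC rhythm channels (deg),
# mean curves from the packaged coupling tables, constant 4 deg SD;
# approximate stand-in for in vivo bone-pin envelopes.
channel	elevation	mean	sd
sc_elevation	20	4	4
sc_elevation	30	5.21	4
sc_elevation	40	6.5	4
sc_elevation	50	7.932	4
sc_elevation	60	9.5	4
sc_elevation	70	11.186	4
sc_elevation	80	13	4
sc_elevation	90	14.949	4
sc_elevation	100	17	4
sc_elevation	110	19.082	4
sc_elevation	120	21	4
sc_elevation	130	22.598	4
sc_elevation	140	24	4
sc_protraction	20	-15	4
sc_protraction	30	-15.96	4
sc_protraction	40	-17	4
sc_protraction	50	-18.182	4
sc_protraction	60	-19.5	4
sc_protraction	70	-20.936	4
sc_protraction	80	-22.5	4
sc_protraction	90	-24.199	4
sc_protraction	100	-26	4
sc_protraction	110	-27.832	4
sc_protraction	120	-29.5	4
sc_protraction	130	-30.848	4
sc_protraction	140	-32	4
sc_axial	20	0	4
sc_axial	30	0.88	4
sc_axial	40	2	4
sc_axial	50	3.547	4
sc_axial	60	5.5	4
sc_axial	70	7.808	4
sc_axial	80	10.5	4
sc_axial	90	13.596	4
sc_axial	100	17	4
sc_axial	110	20.559	4
sc_axial	120	24	4
sc_axial	130	27.105	4
sc_axial	140	30	4
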