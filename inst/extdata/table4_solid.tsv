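form	molecule	R	beta	Phi	phi1	phi2	phi3	phi4	phi5	Phi_equals_phi1
dimer	A	5.150	127.9	-82.1	-82.1	-70.4	-168.4	71.9	-168.8	TRUE
dimer	B	5.148	127.9	-88.8	-88.8	-70.3	-168.1	71.8	-168.9	TRUE
tetramer	A	5.148	128.6	-82.3	-82.3	-70.4	-167.3	72.5	-167.4	TRUE
tetramer	B	5.212	117.2	-80.1	-80.1	-76.3	176.8	64.2	-90.8	TRUE
tetramer	C	5.110	122.0	158.6	158.6	-71.7	-50.5	60.1	-53.8	TRUE
tetramer	D	4.313	150.6	-95.3	-95.3	-93.1	-100.2	70.6	-160.4	TRUE
xray	A0				-76.5	-76.9	173.2	60.6		FALSE
xray	B				-74.4	-66.3	-176.2	73.5		FALSE
xray	C				-90.5	-173.3	-171.9	-174.4		FALSE
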