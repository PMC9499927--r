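class	phi_min	phi_max	psi_min	psi_max	region
general	-180	-45	60	180	beta/PPII
general	-180	-45	-180	-150	beta-wrap
general	-160	-45	-80	10	alpha-R
general	40	80	0	80	alpha-L
proline	-110	-40	-60	10	alpha-R
proline	-110	-40	100	180	PPII
glycine	-180	-45	60	180	beta/PPII
glycine	-180	-45	-180	-150	beta-wrap
glycine	-160	-45	-80	10	alpha-R
glycine	40	180	-80	80	alpha-L-broad
glycine	45	180	-180	-60	mirror-beta
glycine	45	180	150	180	mirror-beta-wrap
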