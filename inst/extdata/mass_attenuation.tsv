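# Mass attenuation coefficients mu/rho (cm^2/g) for liquid water and cortical
# bone, compiled by the package authors from NIST XCOM tabulations (values
# rounded; log-log interpolation is used between grid points).
energy_keV	water	bone
40	0.2683	0.6655
50	0.2269	0.4242
60	0.2059	0.3148
80	0.1837	0.2229
100	0.1707	0.1855
150	0.1505	0.1480
200	0.1370	0.1309
300	0.1186	0.1113
400	0.1061	0.0992
500	0.0969	0.0905
600	0.0896	0.0836
800	0.0786	0.0734
1000	0.0707	0.0657
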