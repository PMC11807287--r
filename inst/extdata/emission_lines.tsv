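# Photon emission lines (X- and gamma-ray) per decay of the parent isotope.
# Th227: Thorium-227 (gamma lines plus radium K X-rays from internal conversion).
# Ra223chain: Radium-223 in secular equilibrium with its short-lived daughters
#   Rn-219, Po-215, Pb-211, Bi-211 and Tl-207; intensities are photons per
#   Ra-223 decay and include radon K X-rays.
# Compiled by the package authors from public decay-data tabulations
# (NNDC NuDat / ICRP Publication 107); intensities rounded, lines below
# 1e-4 photons/decay omitted at source.
isotope	energy_keV	intensity
Th227	50.13	0.0846
Th227	79.72	0.0189
Th227	85.43	0.0430
Th227	88.47	0.0700
Th227	93.35	0.0120
Th227	99.96	0.0240
Th227	103.00	0.0080
Th227	113.10	0.0064
Th227	204.00	0.0023
Th227	235.96	0.1260
Th227	252.50	0.0068
Th227	256.23	0.0700
Th227	281.42	0.0136
Th227	286.09	0.0174
Th227	289.59	0.0190
Th227	299.98	0.0216
Th227	304.50	0.0116
Th227	312.68	0.0038
Th227	329.85	0.0270
Th227	334.37	0.0109
Ra223chain	81.07	0.1500
Ra223chain	83.79	0.2470
Ra223chain	94.25	0.0870
Ra223chain	97.50	0.0310
Ra223chain	122.32	0.0124
Ra223chain	144.27	0.0336
Ra223chain	154.21	0.0570
Ra223chain	158.63	0.0070
Ra223chain	269.46	0.1390
Ra223chain	271.23	0.1080
Ra223chain	323.87	0.0393
Ra223chain	338.28	0.0279
Ra223chain	342.87	0.0023
Ra223chain	351.07	0.1300
Ra223chain	371.68	0.0049
Ra223chain	401.81	0.0664
Ra223chain	404.85	0.0378
Ra223chain	427.09	0.0176
Ra223chain	445.03	0.0128
Ra223chain	704.64	0.0046
Ra223chain	766.51	0.0062
Ra223chain	831.96	0.0352
Ra223chain	897.80	0.0026
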