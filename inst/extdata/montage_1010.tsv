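channel	x	y	z	ap_deg	lat_deg
Fp1	0.9510565162951535	-0.09549150281252629	0.29389262614623657	72	-18
Fpz	0.9510565162951535	0	0.30901699437494745	72	0
Fp2	0.9510565162951535	0.09549150281252629	0.29389262614623657	72	18
AF7	0.8090169943749475	-0.5590169943749475	0.18163563200134025	54	-72
AF3	0.8090169943749475	-0.3454915028125263	0.4755282581475768	54	-36
AFz	0.8090169943749475	0	0.5877852522924731	54	0
AF4	0.8090169943749475	0.3454915028125263	0.4755282581475768	54	36
AF8	0.8090169943749475	0.5590169943749475	0.18163563200134025	54	72
F7	0.5877852522924731	-0.7694208842938134	0.25000000000000006	36	-72
F5	0.5877852522924731	-0.6545084971874737	0.4755282581475768	36	-54
F3	0.5877852522924731	-0.4755282581475768	0.6545084971874737	36	-36
F1	0.5877852522924731	-0.24999999999999997	0.7694208842938134	36	-18
Fz	0.5877852522924731	0	0.8090169943749475	36	0
F2	0.5877852522924731	0.24999999999999997	0.7694208842938134	36	18
F4	0.5877852522924731	0.4755282581475768	0.6545084971874737	36	36
F6	0.5877852522924731	0.6545084971874737	0.4755282581475768	36	54
F8	0.5877852522924731	0.7694208842938134	0.25000000000000006	36	72
FT7	0.3090169943749474	-0.9045084971874736	0.29389262614623657	18	-72
FC5	0.3090169943749474	-0.7694208842938134	0.5590169943749475	18	-54
FC3	0.3090169943749474	-0.5590169943749475	0.7694208842938134	18	-36
FC1	0.3090169943749474	-0.2938926261462365	0.9045084971874736	18	-18
FCz	0.3090169943749474	0	0.9510565162951535	18	0
FC2	0.3090169943749474	0.2938926261462365	0.9045084971874736	18	18
FC4	0.3090169943749474	0.5590169943749475	0.7694208842938134	18	36
FC6	0.3090169943749474	0.7694208842938134	0.5590169943749475	18	54
FT8	0.3090169943749474	0.9045084971874736	0.29389262614623657	18	72
T7	0	-0.9510565162951535	0.30901699437494745	0	-72
C5	0	-0.8090169943749475	0.5877852522924731	0	-54
C3	0	-0.5877852522924731	0.8090169943749475	0	-36
C1	0	-0.3090169943749474	0.9510565162951535	0	-18
Cz	0	0	1	0	0
C2	0	0.3090169943749474	0.9510565162951535	0	18
C4	0	0.5877852522924731	0.8090169943749475	0	36
C6	0	0.8090169943749475	0.5877852522924731	0	54
T8	0	0.9510565162951535	0.30901699437494745	0	72
TP9	-0.3090169943749474	-0.9510565162951535	5.823541592445462e-17	-18	-90
TP7	-0.3090169943749474	-0.9045084971874736	0.29389262614623657	-18	-72
CP5	-0.3090169943749474	-0.7694208842938134	0.5590169943749475	-18	-54
CP3	-0.3090169943749474	-0.5590169943749475	0.7694208842938134	-18	-36
CP1	-0.3090169943749474	-0.2938926261462365	0.9045084971874736	-18	-18
CPz	-0.3090169943749474	0	0.9510565162951535	-18	0
CP2	-0.3090169943749474	0.2938926261462365	0.9045084971874736	-18	18
CP4	-0.3090169943749474	0.5590169943749475	0.7694208842938134	-18	36
CP6	-0.3090169943749474	0.7694208842938134	0.5590169943749475	-18	54
TP8	-0.3090169943749474	0.9045084971874736	0.29389262614623657	-18	72
TP10	-0.3090169943749474	0.9510565162951535	5.823541592445462e-17	-18	90
P7	-0.5877852522924731	-0.7694208842938134	0.25000000000000006	-36	-72
P5	-0.5877852522924731	-0.6545084971874737	0.4755282581475768	-36	-54
P3	-0.5877852522924731	-0.4755282581475768	0.6545084971874737	-36	-36
P1	-0.5877852522924731	-0.24999999999999997	0.7694208842938134	-36	-18
Pz	-0.5877852522924731	0	0.8090169943749475	-36	0
P2	-0.5877852522924731	0.24999999999999997	0.7694208842938134	-36	18
P4	-0.5877852522924731	0.4755282581475768	0.6545084971874737	-36	36
P6	-0.5877852522924731	0.6545084971874737	0.4755282581475768	-36	54
P8	-0.5877852522924731	0.7694208842938134	0.25000000000000006	-36	72
PO7	-0.8090169943749475	-0.5590169943749475	0.18163563200134025	-54	-72
PO3	-0.8090169943749475	-0.3454915028125263	0.4755282581475768	-54	-36
POz	-0.8090169943749475	0	0.5877852522924731	-54	0
PO4	-0.8090169943749475	0.3454915028125263	0.4755282581475768	-54	36
PO8	-0.8090169943749475	0.5590169943749475	0.18163563200134025	-54	72
O1	-0.9510565162951535	-0.09549150281252629	0.29389262614623657	-72	-18
Oz	-0.9510565162951535	0	0.30901699437494745	-72	0
O2	-0.9510565162951535	0.09549150281252629	0.29389262614623657	-72	18
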