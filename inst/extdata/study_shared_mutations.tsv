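# Shared mtDNA mutations across tissues of the same patient, as published:
# table "somatic" lists somatic mutations (absent from benign tissue) found
# in more than one tissue sample; table "germline" lists shared mutations
# regarded as germline.  Cells are the percentage of the mutated nucleotide
# (relative to the rCRS); n.a. = tissue not available, n.d. = heteroplasmy
# not detected above the 1% threshold.
table	patient	mutation	benign	blood	primary_tumor	recurrence	lymph_node_metastasis
somatic	MKG05	m.C64Y	n.d.	n.d.	12.13	62.3	n.a.
somatic	MKG05	m.A5894R	n.d.	n.d.	15.54	71.6	n.a.
somatic	MKG05	m.G6762R	n.d.	n.d.	7.14	1.2	n.a.
somatic	MKG05	m.G10310R	n.d.	n.d.	10.8	61.2	n.a.
somatic	MKG10	m.T9865Y	n.d.	n.a.	1.76	1.6	n.a.
somatic	MKG15	m.C5297Y	n.d.	n.a.	45.87	n.a.	84.8
somatic	MKG15	m.G9565R	n.d.	n.a.	12.41	n.a.	55.1
somatic	MKG15	m.G12868R	n.d.	n.a.	37.8	n.a.	85.8
somatic	MKG20	m.G2916R	n.d.	n.a.	21.02	n.a.	31.5
somatic	MKG20	m.G12736R	n.d.	n.a.	24.73	n.a.	32
somatic	MKG27	m.A183R	n.d.	n.a.	22.7	n.a.	57.5
somatic	MKG27	m.T13897Y	n.d.	n.a.	2.4	n.a.	1.9
germline	MKG01	m.G14560R	1.65	n.a.	1.38	n.a.	n.a.
germline	MKG04	m.T5789Y	16.91	45.62	8.21	n.a.	n.a.
germline	MKG05	m.C16261Y	1.27	n.d.	87.02	74.8	n.a.
germline	MKG06	m.G8865R	27.74	20.86	65.87	n.a.	n.a.
germline	MKG07	m.T16093Y	22.39	n.a.	10.58	n.a.	n.a.
germline	MKG08	m.G15355R	52.08	56.66	10.37	n.a.	n.a.
germline	MKG11	m.T146Y	98.73	45.16	n.a.	n.a.	n.a.
germline	MKG13	m.C13287Y	3.53	n.a.	1.38	1.7	n.a.
germline	MKG13	m.T5814Y	6.73	n.a.	4.15	5.3	n.a.
germline	MKG15	m.A9794R	2.84	n.a.	1.63	n.a.	74.7
germline	MKG17	m.G15498R	23.73	n.a.	30.5	n.a.	n.a.
germline	MKG21	m.G13759R	2.66	n.a.	1.26	1.54	n.a.
germline	MKG21	m.C16465Y	89.32	n.a.	41.85	43.35	n.a.
germline	MKG22	m.C16148Y	30.5	n.a.	6.17	n.a.	n.a.
germline	MKG23	m.T4597Y	1.28	n.a.	1.3	n.a.	n.a.
germline	MKG27	m.A16241R	1.1	n.a.	1.14	n.a.	n.d.
germline	MKG27	m.A9702R	8.6	n.a.	25.4	n.a.	58.9
germline	MKG27	m.A215R	24	n.a.	32.5	n.a.	56.7
germline	MKG28	m.C64Y	6.83	n.a.	3.33	n.a.	n.a.
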