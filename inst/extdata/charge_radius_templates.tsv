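resname	atom	charge	radius	hbond_role	formal_charge
GAL	C1	0.08	1.70	none	0
GAL	C2	-0.10	1.70	none	0
GAL	C3	0.12	1.70	none	0
GAL	C4	0.12	1.70	none	0
GAL	C5	0.12	1.70	none	0
GAL	C6	-0.10	1.70	none	0
GAL	C7	0.52	1.70	none	0
GAL	O1	-0.44	1.50	acceptor	0
GAL	O2	-0.38	1.50	both	0
GAL	HO2	0.30	1.00	none	0
GAL	O3	-0.40	1.50	both	0
GAL	HO3	0.32	1.00	none	0
GAL	O4	-0.40	1.50	both	0
GAL	HO4	0.32	1.00	none	0
GAL	O5	-0.40	1.50	both	0
GAL	HO5	0.32	1.00	none	0
HID	N	-0.30	1.50	donor	0
HID	H1	0.33	1.00	none	0
HID	H2	0.33	1.00	none	0
HID	H3	0.33	1.00	none	0
HID	CA	0.21	1.70	none	0
HID	C	0.52	1.70	none	0
HID	O	-0.56	1.50	acceptor	0
HID	OXT	-0.56	1.50	acceptor	0
HID	CB	-0.05	1.70	none	0
HID	CG	0.10	1.70	none	0
HID	ND1	-0.36	1.50	donor	0
HID	HD1	0.36	1.00	none	0
HID	CD2	-0.12	1.70	none	0
HID	CE1	0.22	1.70	none	0
HID	NE2	-0.45	1.50	acceptor	0
HIP	N	-0.30	1.50	donor	1
HIP	H1	0.33	1.00	none	1
HIP	H2	0.33	1.00	none	1
HIP	H3	0.33	1.00	none	1
HIP	CA	0.21	1.70	none	1
HIP	C	0.52	1.70	none	1
HIP	O	-0.56	1.50	acceptor	1
HIP	OXT	-0.56	1.50	acceptor	1
HIP	CB	-0.05	1.70	none	1
HIP	CG	0.15	1.70	none	1
HIP	ND1	-0.30	1.50	donor	1
HIP	HD1	0.40	1.00	none	1
HIP	CD2	0.10	1.70	none	1
HIP	CE1	0.30	1.70	none	1
HIP	NE2	-0.30	1.50	donor	1
HIP	HE2	0.40	1.00	none	1
ION	ION	1.00	2.00	none	1
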