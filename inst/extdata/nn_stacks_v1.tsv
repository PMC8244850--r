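pair1	pair2	dg37	dh
AU	AU	-0.93	-6.82
AU	UA	-1.10	-9.38
UA	AU	-1.33	-7.69
CG	UA	-2.08	-10.48
CG	AU	-2.11	-10.44
GC	UA	-2.24	-11.40
GC	AU	-2.35	-12.44
CG	GC	-2.36	-10.64
GC	GC	-3.26	-13.39
GC	CG	-3.42	-14.88
AU	GU	-0.55	-3.21
AU	UG	-1.36	-8.81
UA	GU	-1.00	-7.00
UA	UG	-1.00	-7.00
CG	GU	-1.41	-5.61
CG	UG	-2.11	-12.11
GC	GU	-1.53	-8.33
GC	UG	-2.51	-12.59
GU	GU	-0.50	-13.47
GU	UG	1.29	-9.26
UG	GU	-0.57	-9.06
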