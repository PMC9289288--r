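MECHANICAL_AXIS	curated cytoskeletal-nuclear mechanical axis (lamins, actins, tubulins, LINC complex, nuclear pore complex and associated factors); 55 genes	LMNA	LMNB1	LMNB2	ACTB	ACTG1	TUBA1A	TUBB	SYNE1	SYNE2	SYNE3	SYNE4	SUN1	SUN2	EMD	TPR	POM121	POM121C	RAE1	NDC1	AAAS	SEH1L	SEC13	NUP35	NUP37	NUP43	NUP50	NUP54	NUP58	NUP62	NUP85	NUP88	NUP93	NUP98	NUP107	NUP133	NUP153	NUP155	NUP160	NUP188	NUP205	NUP210	NUP214	RANBP2	NUPL2	IPO5	IPO7	NXF1	RAN	RCC1	HSPA8	VIM	UBE2I	SENP2	RANBP1	RANGAP1
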