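sample_id	species	its	igs	nlsu	mtssu	tef1
SYAU-FUNGI-022	Lepista densifolia	1	1	0	1	0
SYAU-FUNGI-023	Lepista irina	1	1	1	1	1
SYAU-FUNGI-024	Lepista irina	1	1	1	1	1
SYAU-FUNGI-025	Lepista irina	1	0	1	1	0
SYAU-FUNGI-021	Lepista nuda	1	1	1	1	1
SYAU-FUNGI-026	Lepista nuda	1	0	0	0	1
SYAU-FUNGI-017	Lepista nuda	1	1	1	1	1
SYAU-FUNGI-019	Lepista nuda	1	0	1	1	1
SYAU-FUNGI-027	Lepista nuda	1	1	1	1	1
SYAU-FUNGI-014	Lepista nuda	1	1	1	1	1
SYAU-FUNGI-028	Lepista nuda	1	0	1	1	1
SYAU-FUNGI-029	Lepista nuda	1	1	0	1	1
SYAU-FUNGI-030	Lepista panaeola	1	1	0	1	0
SYAU-FUNGI-031	Lepista panaeola	1	0	0	0	0
SYAU-FUNGI-032	Lepista panaeola	1	1	0	1	1
SYAU-FUNGI-033	Lepista panaeola	1	1	1	1	0
SYAU-FUNGI-034	Lepista panaeola	1	1	1	1	0
SYAU-FUNGI-035	Lepista panaeola	1	1	1	1	1
SYAU-FUNGI-036	Lepista saeva	1	1	1	1	0
SYAU-FUNGI-037	Lepista saeva	1	1	1	1	0
SYAU-FUNGI-038	Lepista saeva	1	1	1	1	0
SYAU-FUNGI-039	Lepista sordida	1	1	1	1	1
SYAU-FUNGI-040	Lepista sordida	1	1	0	1	0
SYAU-FUNGI-041	Lepista sordida	1	1	1	1	0
SYAU-FUNGI-042	Lepista sordida	1	1	1	1	1
SYAU-FUNGI-043	Lepista sordida	1	1	1	1	1
SYAU-FUNGI-044	Lepista sordida	1	1	1	1	1
SYAU-FUNGI-045	Lepista sp 1	1	0	0	0	1
SYAU-FUNGI-046	Lepista sp 1	1	0	1	0	1
SYAU-FUNGI-047	Lepista sp 1	1	1	1	1	1
SYAU-FUNGI-048	Lepista sp 1	1	1	1	1	1
SYAU-FUNGI-049	Lepista sp 1	1	1	0	1	1
SYAU-FUNGI-050	Lepista sp 2	1	1	0	0	0
SYAU-FUNGI-051	Lepista sp 2	1	1	1	0	0
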