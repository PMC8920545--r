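OSTEOBLAST_DIFFERENTIATION_1	synthetic stand-in gene set	OSG065	OSG074	OSG146	OSG122	OSG049	OSG128	OSG047	OSG024	OSG071	OSG100
OSTEOBLAST_DIFFERENTIATION_2	synthetic stand-in gene set	OSG110	OSG020	OSG114	OSG111	OSG131	OSG041	OSG089	OSG027	OSG109	OSG005	OSG092	OSG104	OSG003	OSG058	OSG042	OSG024	OSG043	OSG137
OSTEOBLAST_DIFFERENTIATION_3	synthetic stand-in gene set	OSG036	OSG068	OSG146	OSG109	OSG092	OSG004	OSG099	OSG114	OSG006	OSG134	OSG130	OSG116	OSG003	OSG118	OSG002	OSG102	OSG040
OSTEOBLAST_DIFFERENTIATION_4	synthetic stand-in gene set	OSG033	OSG103	OSG109	OSG073	OSG076	OSG009	OSG035	OSG016	OSG101	OSG069	OSG118	OSG130	OSG082	OSG113
OSTEOBLAST_DIFFERENTIATION_5	synthetic stand-in gene set	OSG069	OSG110	OSG104	OSG040	OSG057	OSG100	OSG042	OSG091	OSG013	OSG054	OSG083
OSTEOBLAST_DIFFERENTIATION_6	synthetic stand-in gene set	OSG060	OSG029	OSG081	OSG108	OSG121	OSG085	OSG126	OSG112	OSG072	OSG149	OSG001	OSG133	OSG055	OSG043	OSG042	OSG136	OSG097	OSG025	OSG115	OSG032	OSG148	OSG014	OSG111	OSG006	OSG120
OSTEOBLAST_DIFFERENTIATION_7	synthetic stand-in gene set	OSG043	OSG113	OSG149	OSG031	OSG094	OSG006	OSG038	OSG095	OSG145	OSG084	OSG015	OSG034	OSG012	OSG128	OSG041	OSG066	OSG056	OSG098	OSG025	OSG092	OSG107	OSG061	OSG062	OSG014
OSTEOBLAST_DIFFERENTIATION_8	synthetic stand-in gene set	OSG124	OSG095	OSG032	OSG138	OSG028	OSG118	OSG037	OSG147	OSG113	OSG005	OSG035
OSTEOBLAST_DIFFERENTIATION_9	synthetic stand-in gene set	OSG014	OSG122	OSG097	OSG127	OSG031	OSG043	OSG081	OSG027	OSG030	OSG100	OSG075	OSG062	OSG013	OSG126	OSG124	OSG063	OSG049	OSG061	OSG116	OSG001	OSG028	OSG002	OSG146
OSTEOBLAST_TRANSCRIPTION_FACTOR_RUNX_LIKE	synthetic stand-in gene set	OSG127	OSG003	OSG013	OSG012	OSG051	OSG095	OSG047	OSG056	OSG010	OSG149	OSG082	OSG028	OSG093	OSG057	OSG084	OSG118	OSG061
OSTEOBLAST_DEVELOPMENT	synthetic stand-in gene set	OSG150	OSG054	OSG055	OSG149	OSG058	OSG043	OSG085	OSG102	OSG142	OSG049	OSG139	OSG018	OSG148	OSG036	OSG071
OSTEOBLAST_PROLIFERATION_1	synthetic stand-in gene set	OSG027	OSG094	OSG133	OSG086	OSG114	OSG139	OSG038	OSG106	OSG127	OSG090
OSTEOBLAST_PROLIFERATION_2	synthetic stand-in gene set	OSG105	OSG011	OSG147	OSG036	OSG059	OSG113	OSG030	OSG108	OSG047	OSG150	OSG088	OSG114
OSTEOBLAST_PROLIFERATION_3	synthetic stand-in gene set	OSG135	OSG142	OSG012	OSG051	OSG010	OSG121	OSG089	OSG037	OSG027	OSG046	OSG031	OSG091	OSG100	OSG120	OSG053	OSG024
OSTEOBLAST_SIGNALING	synthetic stand-in gene set	OSG148	OSG123	OSG092	OSG033	OSG093	OSG036	OSG045	OSG096	OSG102	OSG135	OSG108	OSG005	OSG122	OSG030	OSG054
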