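PCNA_SIGNATURE_SYNTHETIC	synthetic stand-in proliferation signature; r>0.65 with PCNA in normal tissues	PCS001	PCS002	PCS003	PCS004	PCS005	PCS006	PCS007	PCS008	PCS009	PCS010	PCS011	PCS012	PCS013	PCS014	PCS015	PCS016	PCS017	PCS018	PCS019	PCS020	PCS021	PCS022	PCS023	PCS024	PCS025	PCS026	PCS027	PCS028	PCS029	PCS030	PCS031	PCS032	PCS033	PCS034	PCS035	PCS036	PCS037	PCS038	PCS039	PCS040	PCS041	PCS042	PCS043	PCS044	PCS045	PCS046	PCS047	PCS048	PCS049	PCS050	PCS051	PCS052	PCS053	PCS054	PCS055	PCS056	PCS057	PCS058	PCS059	PCS060	PCS061	PCS062	PCS063	PCS064	PCS065	PCS066	PCS067	PCS068	PCS069	PCS070	PCS071	PCS072	PCS073	PCS074	PCS075	PCS076	PCS077	PCS078	PCS079	PCS080	PCS081	PCS082	PCS083	PCS084	PCS085	PCS086	PCS087	PCS088	PCS089	PCS090	PCS091	PCS092	PCS093	PCS094	PCS095	PCS096	PCS097	PCS098	PCS099	PCS100	PCS101	PCS102	PCS103	PCS104	PCS105	PCS106	PCS107	PCS108	PCS109	PCS110	PCS111	PCS112	PCS113	PCS114	PCS115	PCS116	PCS117	PCS118	PCS119	PCS120	PCS121	PCS122	PCS123	PCS124	PCS125	PCS126	PCS127	PCS128	PCS129	PCS130	PCS131
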