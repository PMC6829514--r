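# Synthetic demo catalogue bundled with the pepscreen package.
# Literature-typical short bioactive peptides for tests and examples only;
# this is NOT a copy of BIOPEP-UWM or any other hosted database.
id	sequence	activity	reference
demo001	VY	ACE inhibitor	synthetic demo entry
demo002	IY	ACE inhibitor	synthetic demo entry
demo003	IW	ACE inhibitor	synthetic demo entry
demo004	VW	ACE inhibitor	synthetic demo entry
demo005	AW	ACE inhibitor	synthetic demo entry
demo006	GY	ACE inhibitor	synthetic demo entry
demo007	RY	ACE inhibitor	synthetic demo entry
demo008	KW	ACE inhibitor	synthetic demo entry
demo009	LW	ACE inhibitor	synthetic demo entry
demo010	LY	ACE inhibitor	synthetic demo entry
demo011	AF	ACE inhibitor	synthetic demo entry
demo012	VF	ACE inhibitor	synthetic demo entry
demo013	IF	ACE inhibitor	synthetic demo entry
demo014	YP	ACE inhibitor	synthetic demo entry
demo015	RP	ACE inhibitor	synthetic demo entry
demo016	EA	ACE inhibitor	synthetic demo entry
demo017	KY	ACE inhibitor	synthetic demo entry
demo018	HL	ACE inhibitor	synthetic demo entry
demo019	AL	ACE inhibitor	synthetic demo entry
demo020	GF	ACE inhibitor	synthetic demo entry
demo021	SF	ACE inhibitor	synthetic demo entry
demo022	TF	ACE inhibitor	synthetic demo entry
demo023	NY	ACE inhibitor	synthetic demo entry
demo024	DY	ACE inhibitor	synthetic demo entry
demo025	MF	ACE inhibitor	synthetic demo entry
demo026	EY	ACE inhibitor	synthetic demo entry
demo027	PL	ACE inhibitor	synthetic demo entry
demo028	QF	ACE inhibitor	synthetic demo entry
demo029	CF	ACE inhibitor	synthetic demo entry
demo030	WL	ACE inhibitor	synthetic demo entry
demo031	FY	ACE inhibitor	synthetic demo entry
demo032	AY	ACE inhibitor	synthetic demo entry
demo033	GW	ACE inhibitor	synthetic demo entry
demo034	SW	ACE inhibitor	synthetic demo entry
demo035	VE	ACE inhibitor	synthetic demo entry
demo036	IE	ACE inhibitor	synthetic demo entry
demo037	IPP	ACE inhibitor	synthetic demo entry
demo038	VPP	ACE inhibitor	synthetic demo entry
demo039	LKP	ACE inhibitor	synthetic demo entry
demo040	IKP	ACE inhibitor	synthetic demo entry
demo041	LRP	ACE inhibitor	synthetic demo entry
demo042	IRP	ACE inhibitor	synthetic demo entry
demo043	IKW	ACE inhibitor	synthetic demo entry
demo044	LQP	ACE inhibitor	synthetic demo entry
demo045	FQP	ACE inhibitor	synthetic demo entry
demo046	GPL	ACE inhibitor	synthetic demo entry
demo047	VAP	ACE inhibitor	synthetic demo entry
demo048	IVY	ACE inhibitor	synthetic demo entry
demo049	LVY	ACE inhibitor	synthetic demo entry
demo050	YLV	ACE inhibitor	synthetic demo entry
demo051	AHL	ACE inhibitor	synthetic demo entry
demo052	GPV	ACE inhibitor	synthetic demo entry
demo053	VSV	ACE inhibitor	synthetic demo entry
demo054	LSW	ACE inhibitor	synthetic demo entry
demo055	IRW	ACE inhibitor	synthetic demo entry
demo056	LAY	ACE inhibitor	synthetic demo entry
demo057	VGL	ACE inhibitor	synthetic demo entry
demo058	FAL	ACE inhibitor	synthetic demo entry
demo059	VKL	ACE inhibitor	synthetic demo entry
demo060	GKF	ACE inhibitor	synthetic demo entry
demo061	AKF	ACE inhibitor	synthetic demo entry
demo062	AE	DPP-IV inhibitor	synthetic demo entry
demo063	GP	DPP-IV inhibitor	synthetic demo entry
demo064	PG	DPP-IV inhibitor	synthetic demo entry
demo065	IP	DPP-IV inhibitor	synthetic demo entry
demo066	VP	DPP-IV inhibitor	synthetic demo entry
demo067	LP	DPP-IV inhibitor	synthetic demo entry
demo068	MP	DPP-IV inhibitor	synthetic demo entry
demo069	FP	DPP-IV inhibitor	synthetic demo entry
demo070	WP	DPP-IV inhibitor	synthetic demo entry
demo071	HP	DPP-IV inhibitor	synthetic demo entry
demo072	KP	DPP-IV inhibitor	synthetic demo entry
demo073	AP	DPP-IV inhibitor	synthetic demo entry
demo074	SP	DPP-IV inhibitor	synthetic demo entry
demo075	TP	DPP-IV inhibitor	synthetic demo entry
demo076	EP	DPP-IV inhibitor	synthetic demo entry
demo077	QP	DPP-IV inhibitor	synthetic demo entry
demo078	NP	DPP-IV inhibitor	synthetic demo entry
demo079	DP	DPP-IV inhibitor	synthetic demo entry
demo080	WV	DPP-IV inhibitor	synthetic demo entry
demo081	VA	DPP-IV inhibitor	synthetic demo entry
demo082	LA	DPP-IV inhibitor	synthetic demo entry
demo083	GA	DPP-IV inhibitor	synthetic demo entry
demo084	PA	DPP-IV inhibitor	synthetic demo entry
demo085	PP	DPP-IV inhibitor	synthetic demo entry
demo086	PQ	DPP-IV inhibitor	synthetic demo entry
demo087	PF	DPP-IV inhibitor	synthetic demo entry
demo088	WI	DPP-IV inhibitor	synthetic demo entry
demo089	WA	DPP-IV inhibitor	synthetic demo entry
demo090	ML	DPP-IV inhibitor	synthetic demo entry
demo091	VL	DPP-IV inhibitor	synthetic demo entry
demo092	IPI	DPP-IV inhibitor	synthetic demo entry
demo093	VPL	DPP-IV inhibitor	synthetic demo entry
demo094	LPL	DPP-IV inhibitor	synthetic demo entry
demo095	IPA	DPP-IV inhibitor	synthetic demo entry
demo096	GPA	DPP-IV inhibitor	synthetic demo entry
demo097	APG	DPP-IV inhibitor	synthetic demo entry
demo098	GPG	DPP-IV inhibitor	synthetic demo entry
demo099	PGP	DPP-IV inhibitor	synthetic demo entry
demo100	VPG	DPP-IV inhibitor	synthetic demo entry
demo101	LPG	DPP-IV inhibitor	synthetic demo entry
demo102	IPG	DPP-IV inhibitor	synthetic demo entry
demo103	WPL	DPP-IV inhibitor	synthetic demo entry
demo104	FPL	DPP-IV inhibitor	synthetic demo entry
demo105	HPL	DPP-IV inhibitor	synthetic demo entry
demo106	KPL	DPP-IV inhibitor	synthetic demo entry
demo107	TPL	DPP-IV inhibitor	synthetic demo entry
demo108	SPL	DPP-IV inhibitor	synthetic demo entry
demo109	YY	antioxidative	synthetic demo entry
demo110	LH	antioxidative	synthetic demo entry
demo111	AH	antioxidative	synthetic demo entry
demo112	HH	antioxidative	synthetic demo entry
demo113	WY	antioxidative	synthetic demo entry
demo114	LHA	antioxidative	synthetic demo entry
demo115	AYL	antioxidative	synthetic demo entry
demo116	HLY	antioxidative	synthetic demo entry
demo117	IRL	antibacterial	synthetic demo entry
demo118	KRL	antibacterial	synthetic demo entry
demo119	RW	antibacterial	synthetic demo entry
demo120	KW	antibacterial	synthetic demo entry
demo121	PGG	antithrombotic	synthetic demo entry
demo122	GPR	antithrombotic	synthetic demo entry
demo123	RGD	antithrombotic	synthetic demo entry
demo124	PG	antiamnestic	synthetic demo entry
demo125	GVG	antiamnestic	synthetic demo entry
demo126	YG	neuropeptide	synthetic demo entry
demo127	YGG	neuropeptide	synthetic demo entry
demo128	GFL	neuropeptide	synthetic demo entry
demo129	IW	renin inhibitor	synthetic demo entry
demo130	LW	renin inhibitor	synthetic demo entry
demo131	RF	renin inhibitor	synthetic demo entry
demo132	EW	immunomodulating	synthetic demo entry
demo133	GLF	immunomodulating	synthetic demo entry
demo134	QGP	immunomodulating	synthetic demo entry
demo135	EE	stimulating	synthetic demo entry
demo136	ES	stimulating	synthetic demo entry
demo137	SE	stimulating	synthetic demo entry
demo138	DY	regulating	synthetic demo entry
demo139	YD	regulating	synthetic demo entry
demo140	PGL	regulating	synthetic demo entry
demo141	WE	alpha glucosidase inhibitor	synthetic demo entry
demo142	SWE	alpha glucosidase inhibitor	synthetic demo entry
demo143	LA	activating ubiquitin-mediated proteolysis	synthetic demo entry
demo144	RA	activating ubiquitin-mediated proteolysis	synthetic demo entry
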