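sequence	mw	svm_score	peptideranker_score	allergen
AANITVPAAN	940.4978	-1.3	0.144457	allergen
AAPPPN	565.627	-0.46	0.792864	allergen
AGD	261.235	-0.8	0.283992	allergen
AGGPNQPPN	850.3933	-0.72	0.621643	allergen
CGD	293.295	-0.79	0.646691	allergen
DD	248.192	-0.79	0.098852	allergen
DDA	319.271	-0.8	0.127455	allergen
DEVIPGA	699.759	-0.45	0.185675	allergen
EVH	383.404	-0.82	0.0380427	allergen
GASPVT	530.579	-0.97	0.247962	allergen
GESS	378.339	-0.76	0.0716116	allergen
GGAPQH	565.586	-0.86	0.388533	allergen
GSASGA	448.433	-0.93	0.250858	allergen
GSECM	525.592	-0.42	0.554283	allergen
IDVA	416.475	-0.84	0.0871288	allergen
IECC	466.568	-0.25	0.448357	allergen
IITN	459.543	-0.84	0.106012	allergen
IK	259.349	-0.8	0.0974139	allergen
INNNK	601.66	-0.81	0.0938778	allergen
NGNAASPGQPPL	1122.203	-0.78	0.505873	allergen
NQVTN	574.591	-1.01	0.0559664	allergen
SAIGGAPDG	743.771	-0.67	0.397354	allergen
SAR	332.36	-0.81	0.278711	allergen
TGR	332.36	-0.8	0.276659	allergen
TPAL	400.475	-0.8	0.342157	allergen
VAM	319.419	-0.8	0.264259	allergen
VSQ	332.357	-0.83	0.0492778	allergen
VVPK	441.571	-0.88	0.0810705	allergen
AAAL	344.411	-0.84	0.28869	non_allergen
AAGAAP	456.499	-1.01	0.352249	non_allergen
AAK	288.347	-0.77	0.113614	non_allergen
AAL	273.332	-0.84	0.310569	non_allergen
AAS	247.251	-0.82	0.123531	non_allergen
AM	220.287	-0.8	0.74549	non_allergen
ATKPAN	600.32312	-0.88	0.129647	non_allergen
CN	235.258	-0.8	0.63423	non_allergen
DAT	305.288	-0.81	0.0954274	non_allergen
DAVEI	545.59	-0.93	0.0603561	non_allergen
DEDESS	680.58	-0.78	0.0365686	non_allergen
DS	220.182	-0.8	0.0878061	non_allergen
DSN	334.286	-0.78	0.104772	non_allergen
DVACN	520.558	-0.68	0.203726	non_allergen
EAEPAEAA	394.193	-0.99	0.0830328	non_allergen
ER	303.318	-0.8	0.0704548	non_allergen
GAAPTPPSPPPATKPSTPPKPPT	731.0588	-0.69	0.378489	non_allergen
GAVH	382.42	-0.77	0.173142	non_allergen
GPPPPSP	647.729	-0.11	0.870562	non_allergen
GTF	323.349	-0.8	0.84905	non_allergen
GTSAR	490.517	-0.89	0.151592	non_allergen
IDG	303.315	-0.78	0.288785	non_allergen
INDIEK	730.816	-0.97	0.0849714	non_allergen
IVA	301.386	-0.79	0.0757333	non_allergen
NCA	306.337	-0.77	0.425512	non_allergen
NGGDL	474.471	-0.76	0.567577	non_allergen
PGA	243.263	-0.81	0.674335	non_allergen
PKPPAL	621.778	-0.7	0.715386	non_allergen
PLPP	422.525	-1.04	0.876691	non_allergen
PPNPPNPPN	942.455933	-0.4	0.855282	non_allergen
PVGCL	487.615	-0.63	0.734232	non_allergen
QQQAQM	732.809	-0.92	0.216075	non_allergen
SAAGR	460.49	-0.85	0.341095	non_allergen
SAGVL	445.516	-0.99	0.38464	non_allergen
SAV	275.305	-0.82	0.0814653	non_allergen
SDR	376.37	-0.83	0.242439	non_allergen
SGAASASGAA	748.335144	-1.17	0.2792	non_allergen
SIAGVAA	587.674	-1.28	0.134975	non_allergen
TGGS	320.302	-0.77	0.17105	non_allergen
TPCAVPE	715.819	-0.88	0.224438	non_allergen
VDTAK	532.594	-0.34	0.0513549	non_allergen
VGSTAT	534.567	-1.03	0.0691571	non_allergen
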