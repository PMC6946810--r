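SNP	CHR	POS	A1	A2	EAF	BETA	SE	P	N
rs00001	1	50000	T	A	0.36575	0.370017638779022	0.0223290765201672	1.05929436342184e-59	4000
rs00002	1	100000	A	G	0.26275	0.217896724195893	0.025066569034413	5.08163772512891e-18	4000
rs00003	1	150000	G	A	0.356	0.296245329791712	0.0228040624321605	7.95325762423673e-38	4000
rs00004	1	200000	T	C	0.30125	0.220240344894212	0.024121598843238	1.05828686547121e-19	4000
rs00005	1	250000	T	C	0.158875	0.207514628043042	0.0301683528615925	6.98785155002968e-12	4000
rs00006	1	300000	G	C	0.131125	0.0607000759446682	0.0332979542726104	0.0683875668479118	4000
rs00007	1	350000	A	T	0.156625	-0.00917240523380119	0.0305256625118711	0.763825319917659	4000
rs00008	1	400000	G	C	0.265625	-0.0184487771403615	0.0248345744778441	0.457606064633268	4000
rs00009	1	450000	C	T	0.104	0.00109504707876754	0.0364905588021655	0.976061331784186	4000
rs00010	1	500000	A	G	0.35525	0.147959562251385	0.0230072049280294	1.41685048037208e-10	4000
rs00011	1	550000	C	A	0.4085	0.007943509250417	0.0222697679070291	0.721339161443565	4000
rs00012	1	600000	G	T	0.397125	0.0137907627845593	0.0227186861954151	0.543870185206287	4000
rs00013	1	650000	C	G	0.42725	0.00716715383138855	0.0225809126259647	0.750957616858923	4000
rs00014	1	700000	A	C	0.2695	-0.0128143557169869	0.0249613453267286	0.607722298291758	4000
rs00015	1	750000	C	T	0.264875	-0.000417975567335618	0.0249422472889507	0.986630724019492	4000
rs00016	1	800000	T	G	0.3095	0.036969842452961	0.0243839124587294	0.129558685902129	4000
rs00017	1	850000	A	G	0.484	0.208899406398663	0.0222183705056094	8.75149792486185e-21	4000
rs00018	1	900000	G	A	0.3555	0.00177699281948043	0.0233719088901968	0.939398129908709	4000
rs00019	1	950000	G	T	0.317375	0.0508809868218296	0.0237444188359124	0.0321844658654109	4000
rs00020	1	1000000	A	G	0.19975	0.0532120066168348	0.0278513931762988	0.0561314594763967	4000
rs00021	1	1050000	A	C	0.17325	0.0940205014283088	0.029567761039798	0.00148486576505311	4000
rs00022	1	1100000	A	G	0.1255	0.0145905780240102	0.0331611479279037	0.659968034565385	4000
rs00023	1	1150000	C	A	0.43	0.286634139815453	0.0225583492992004	2.71989964822248e-36	4000
rs00024	1	1200000	T	C	0.474875	0.211398655875086	0.0223818897335669	5.86321161064568e-21	4000
rs00025	1	1250000	G	C	0.4485	0.161311366057625	0.0223770083153667	6.71635112100869e-13	4000
rs00026	1	1300000	T	C	0.16575	-0.0832297998697737	0.0299946066775099	0.00554879513986521	4000
rs00027	1	1350000	A	T	0.233875	-0.0648662266532672	0.0264864745372539	0.0143667088275452	4000
rs00028	1	1400000	T	A	0.382875	-0.0131403757291889	0.0228389086589702	0.565086705694172	4000
rs00029	1	1450000	A	T	0.27	-0.0719891329955974	0.025423459421258	0.00465469163666353	4000
rs00030	1	1500000	C	G	0.30975	-0.222940396196911	0.0239916650063093	2.41395357737114e-20	4000
rs00031	1	1550000	A	C	0.482125	0.00407163627125181	0.0226477462014996	0.857333548534295	4000
rs00032	1	1600000	T	G	0.13225	0.0378381363899143	0.0328633201562509	0.249645203989437	4000
rs00033	1	1650000	G	T	0.47825	0.00118298175364629	0.0226563648738221	0.958360704804486	4000
rs00034	1	1700000	C	G	0.47625	0.0217562679816562	0.0224653364979388	0.332884639677118	4000
rs00035	1	1750000	T	C	0.099625	0.0153826400339293	0.0369577495036047	0.677269674312599	4000
rs00036	1	1800000	A	G	0.247	-0.0637471361015214	0.0255103668737976	0.0124987576037364	4000
rs00037	1	1850000	G	C	0.10525	-0.088059901543529	0.0360824123773731	0.0147092025745635	4000
rs00038	1	1900000	C	G	0.47625	-0.11070929951007	0.0220086208303697	5.11298434607545e-07	4000
rs00039	1	1950000	T	C	0.3075	-0.0774805370811194	0.0236608407358835	0.00106701050061285	4000
rs00040	1	2000000	A	C	0.186625	-0.0705872387175806	0.0285189158435491	0.0133609544290216	4000
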