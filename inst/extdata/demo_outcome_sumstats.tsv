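SNP	CHR	POS	A1	A2	EAF	BETA	SE	P	N
rs00001	1	50000	T	A	0.280375	-0.118150897360448	0.0529834464260179	0.0257501847627082	4000
rs00002	1	100000	A	G	0.412375	-0.0127392711319457	0.0475804800027608	0.788898270150607	4000
rs00003	1	150000	G	A	0.38575	-0.0377777032391592	0.0486520733660077	0.437461484584219	4000
rs00004	1	200000	T	C	0.252125	-0.122592076792522	0.0547525769933525	0.0251546601958707	4000
rs00005	1	250000	T	C	0.35825	-0.114993968826473	0.0496807215461771	0.0206315576095759	4000
rs00006	1	300000	G	C	0.3855	0.0177690115898511	0.048002192973642	0.711255209951678	4000
rs00007	1	350000	A	T	0.364875	-0.0416684800338779	0.0492053019275724	0.397090402884076	4000
rs00008	1	400000	G	C	0.21425	-0.0181831014281881	0.056952179051966	0.749522056338969	4000
rs00009	1	450000	C	T	0.432625	-0.0606638991645646	0.0477630771855533	0.204048901049639	4000
rs00010	1	500000	A	G	0.494125	-0.0517911986647506	0.0477259995749772	0.277842882712636	4000
rs00011	1	550000	C	A	0.108875	0.0614348747159597	0.0749864294354587	0.412626735389514	4000
rs00012	1	600000	G	T	0.431	-0.0241940280053205	0.0466053872353384	0.603673480569039	4000
rs00013	1	650000	C	G	0.33975	-0.00665231036840375	0.0492055284507131	0.89245819913695	4000
rs00014	1	700000	A	C	0.325	0.0104769030726287	0.0508483292616669	0.836757925418062	4000
rs00015	1	750000	C	T	0.4275	-0.00559498928627477	0.0476451983965375	0.906519085139238	4000
rs00016	1	800000	T	G	0.197625	-0.00579761701242114	0.0596410077659962	0.922560763281012	4000
rs00017	1	850000	A	G	0.294875	-0.0153831870909591	0.0523236996867766	0.768757620301366	4000
rs00018	1	900000	G	A	0.434625	0.0426389714520599	0.0475764141460974	0.370134854375533	4000
rs00019	1	950000	G	T	0.476375	0.000778084152050272	0.0473700477775396	0.986894811263914	4000
rs00020	1	1000000	A	G	0.3135	0.0518258010034811	0.0510230751275759	0.309756737191599	4000
rs00021	1	1050000	A	C	0.156375	-0.0231400008435379	0.0647511378268589	0.720816141985043	4000
rs00022	1	1100000	A	G	0.478375	-0.00709943256094639	0.0472119544985606	0.880469851859782	4000
rs00023	1	1150000	C	A	0.255625	-0.0383068256084988	0.0542446280921101	0.480072146815014	4000
rs00024	1	1200000	T	C	0.199125	-0.0271371955376865	0.0591381460804501	0.646321761729564	4000
rs00025	1	1250000	G	C	0.324875	-0.0571526174550139	0.0503743504727412	0.256560599737754	4000
rs00026	1	1300000	T	C	0.46725	0.0416373782572354	0.0473277445139319	0.378985654445361	4000
rs00027	1	1350000	A	T	0.478375	0.0438025688748227	0.0470176896242685	0.351533505646321	4000
rs00028	1	1400000	T	A	0.450625	0.0191127222794908	0.047215985098332	0.685629331743344	4000
rs00029	1	1450000	A	T	0.476375	0.0320909766347074	0.0472935638097251	0.497423985498294	4000
rs00030	1	1500000	C	G	0.422625	0.0715680166020244	0.0472564227781681	0.129908918917006	4000
rs00031	1	1550000	A	C	0.113875	0.0220697511330003	0.0739847586350918	0.76547319719951	4000
rs00032	1	1600000	T	G	0.474	0.0106879591022145	0.0466257940436454	0.818691351254864	4000
rs00033	1	1650000	G	T	0.468375	0.0031910291525565	0.0465156835721474	0.945307107454091	4000
rs00034	1	1700000	C	G	0.4575	-0.00530111485704289	0.0465651531893264	0.909362283044771	4000
rs00035	1	1750000	T	C	0.319875	-0.00446303495235973	0.0501606700529448	0.929101947395928	4000
rs00036	1	1800000	A	G	0.19375	0.103696382851711	0.0594761191086829	0.0812469915893887	4000
rs00037	1	1850000	G	C	0.47275	0.0361098937302784	0.0469594495100887	0.44191762013778	4000
rs00038	1	1900000	C	G	0.20075	0.089227312844977	0.0586957200848142	0.128468939923045	4000
rs00039	1	1950000	T	C	0.47325	0.037129070823292	0.0467450513864125	0.427027322073855	4000
rs00040	1	2000000	A	C	0.279	0.100342370937313	0.0517382600045207	0.0524498533088291	4000
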