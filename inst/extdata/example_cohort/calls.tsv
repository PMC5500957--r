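feature	chromosome	start	end	S001	S002	S003	S004	S005	S006	S007	S008
F00001	1	34978	35037	0	0	0	0	0	0	0	0
F00002	1	70223	70282	0	1	0	0	0	0	0	0
F00003	1	97657	97716	0	1	0	0	0	0	0	0
F00004	1	131622	131681	0	1	0	0	0	0	0	0
F00005	1	163323	163382	0	1	0	0	0	0	0	0
F00006	1	193552	193611	0	0	0	0	0	0	0	0
F00007	1	226391	226450	0	0	0	0	1	-1	-1	0
F00008	1	252007	252066	0	0	0	0	1	-1	-1	0
F00009	1	283891	283950	0	0	0	0	1	-1	-1	0
F00010	1	316352	316411	0	0	0	0	1	-1	-1	0
F00011	1	345845	345904	0	0	0	0	1	-1	-1	0
F00012	1	378474	378533	0	0	0	0	1	-1	-1	0
F00013	1	413690	413749	0	0	0	0	1	-1	-1	1
F00014	1	440755	440814	0	1	0	0	1	-1	-1	1
F00015	1	470303	470362	0	1	0	0	0	-1	-1	1
F00016	1	505583	505642	0	1	0	0	0	-1	0	1
F00017	1	541322	541381	0	1	-1	0	0	-1	0	1
F00018	1	566732	566791	0	1	-1	0	0	-1	0	1
F00019	1	596432	596491	0	1	-1	0	0	-1	0	1
F00020	1	627156	627215	0	1	-1	0	0	-1	0	1
F00021	1	662004	662063	0	1	-1	0	0	-1	0	1
F00022	1	687669	687728	0	1	-1	0	0	-1	0	1
F00023	1	723536	723595	0	1	-1	0	0	-1	0	1
F00024	1	758896	758955	0	1	-1	0	0	-1	0	1
F00025	1	783885	783944	0	1	-1	0	0	-1	0	1
F00026	1	814056	814115	0	1	-1	1	0	-1	0	1
F00027	1	842738	842797	0	1	-1	1	0	-1	0	0
F00028	1	877607	877666	0	1	-1	1	0	-1	0	0
F00029	1	906971	907030	0	1	-1	1	0	-1	0	0
F00030	1	941003	941062	0	0	-1	0	0	-1	0	0
F00031	1	973854	973913	0	0	-1	0	0	-1	0	0
F00032	1	1007587	1007646	0	0	-1	0	0	0	0	0
F00033	1	1036244	1036303	0	0	-1	0	1	0	0	0
F00034	1	1068466	1068525	0	0	-1	0	1	0	0	0
F00035	1	1092513	1092572	0	0	-1	0	1	1	0	1
F00036	1	1126508	1126567	0	0	-1	0	1	1	0	1
F00037	1	1150596	1150655	0	0	-1	0	1	1	0	1
F00038	1	1177088	1177147	0	0	-1	0	1	0	0	1
F00039	1	1211967	1212026	0	1	-1	0	1	-1	0	1
F00040	1	1243308	1243367	0	1	-1	0	1	-1	0	1
F00041	2	28555	28614	0	0	0	0	0	0	0	0
F00042	2	57784	57843	0	0	0	0	0	0	0	0
F00043	2	82233	82292	0	0	0	0	0	0	0	0
F00044	2	117915	117974	0	0	1	0	0	0	0	-1
F00045	2	147096	147155	-1	0	0	0	1	0	0	-1
F00046	2	182587	182646	-1	0	0	0	1	0	0	-1
F00047	2	217240	217299	-1	0	0	0	1	0	0	-1
F00048	2	248920	248979	-1	0	0	0	1	0	0	-1
F00049	2	284572	284631	-1	0	0	0	0	0	0	-1
F00050	2	315998	316057	-1	0	0	0	0	0	0	-1
F00051	2	343999	344058	-1	0	0	0	0	0	0	-1
F00052	2	372160	372219	-1	0	0	0	0	0	0	-1
F00053	2	400942	401001	-1	0	0	0	0	0	0	-1
F00054	2	434358	434417	-1	0	0	0	0	0	0	-1
F00055	2	458825	458884	-1	0	0	0	0	0	0	-1
F00056	2	491811	491870	-1	0	0	0	0	0	0	-1
F00057	2	523938	523997	-1	1	-1	0	0	0	0	-1
F00058	2	549993	550052	-1	1	-1	0	0	0	0	-1
F00059	2	577126	577185	-1	1	-1	1	0	0	0	-1
F00060	2	607299	607358	0	1	-1	1	0	0	0	-1
F00061	2	639406	639465	0	1	-1	1	0	0	0	-1
F00062	2	675200	675259	0	1	-1	1	0	0	0	0
F00063	2	708315	708374	0	1	-1	1	0	0	0	0
F00064	2	739113	739172	0	1	-1	1	0	1	0	0
F00065	2	773309	773368	0	1	-1	0	0	1	0	0
F00066	2	799583	799642	0	1	-1	0	0	1	0	0
F00067	2	826838	826897	0	1	-1	0	0	1	0	0
F00068	2	860776	860835	0	1	-1	0	0	1	0	0
F00069	2	893094	893153	0	1	-1	0	0	1	0	0
F00070	2	919981	920040	0	1	-1	0	0	1	0	0
F00071	2	944497	944556	0	1	-1	0	0	1	0	0
F00072	2	970183	970242	0	1	-1	0	0	1	0	0
F00073	2	996780	996839	0	1	-1	0	0	1	0	0
F00074	2	1026533	1026592	-1	1	-1	0	0	1	0	0
F00075	2	1052902	1052961	0	1	0	0	0	1	0	0
F00076	2	1085534	1085593	0	1	-1	0	0	1	0	0
F00077	2	1109629	1109688	0	1	-1	0	0	1	0	0
F00078	2	1138135	1138194	0	1	-1	0	0	1	0	0
F00079	2	1168308	1168367	0	1	-1	0	0	1	0	0
F00080	2	1192327	1192386	0	1	-1	0	0	1	0	0
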