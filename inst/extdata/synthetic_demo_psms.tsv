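psm_id	spectrum_ref	peptide	is_decoy	xcorr	delta_cn	ions	sprank	calc_neutral_pep_mass	digest_type	truth
psm_00001	spec_00001	NA	0	4.51506596033885	0.234198875913665	11.3660249088209	10.9709867072823	2403.76628391908	2	1
psm_00002	spec_00002	NA	0	3.07481410859513	0.208097431092635	13.7087729213566	4.76883224351557	1852.47238139643	2	1
psm_00003	spec_00003	NA	0	4.17185009822952	0.0963506137081555	10.7737679036859	8.50112299851927	1510.20768972921	2	1
psm_00004	spec_00004	NA	0	3.97026188825846	0.163809509383138	18.0073810244115	9.82371312876275	2241.92593817745	2	1
psm_00005	spec_00005	NA	0	3.44656014095604	0.113100798956596	22.241583877386	8.20757133984156	1611.61355480598	1	1
psm_00006	spec_00006	NA	0	1.78205566590367	0.209701350209071	13.6910352936187	2.81654047925193	1273.6737917195	1	1
psm_00007	spec_00007	NA	0	3.38490367700117	0.133107068784287	15.0213278668033	7.56913113658018	1436.14038607982	1	1
psm_00008	spec_00008	NA	0	3.12842575789059	0.162043932316882	10.6020070364529	8.50005645048839	1762.11118806708	2	1
psm_00009	spec_00009	NA	0	1.90219899716758	0.0334542391988241	16.9791654470481	7.96823299744142	1370.3920867568	0	0
psm_00010	spec_00010	NA	0	1.37358811634391	0.0527331291243889	14.8091444547304	6.50112534062479	1637.57734430604	0	0
psm_00011	spec_00011	NA	0	1.43260676609586	0.129376939709869	4.17860721742061	6.73072359636635	1431.1944041822	0	0
psm_00012	spec_00012	NA	0	1.14261004926575	0.0500663093921501	19.4053850955265	8.42807282035732	942.911337047751	0	0
psm_00013	spec_00013	NA	0	1.60070706053444	0.110097051643075	6.15397424943883	2.87765655673107	1413.09774810565	0	0
psm_00014	spec_00014	NA	0	1.59676512801394	0.131713092975417	6.73993231266822	3.14432107705662	2030.14237136076	0	0
psm_00015	spec_00015	NA	0	-0.492193301515466	0.106084797112982	4.64077237585488	4.97505741157263	1367.19513080976	0	0
psm_00016	spec_00016	NA	0	3.01230134936733	0.0996154968335532	6.03281539617907	6.01675920185807	1323.34067939953	0	0
psm_00017	spec_00017	NA	0	2.35476733126497	-0.00140779239745017	10.2601028765403	9.21621889654049	1463.82352249413	1	0
psm_00018	spec_00018	NA	0	1.9958079044771	0.100909016778718	14.6641127157471	2.4041904429121	1995.91838455854	1	0
psm_00019	spec_00019	NA	0	1.07575305263976	-0.00599506371877764	8.44505712074579	2.37813813013972	1238.59362941108	0	0
psm_00020	spec_00020	NA	0	2.42077209986324	0.200691868376213	11.005054311838	7.3229546024747	1734.20048125733	1	0
psm_00021	spec_00021	NA	0	1.50419518731878	0.0497676360085597	10.5931333824077	3.79432927544824	1315.8366392044	0	0
psm_00022	spec_00022	NA	0	1.65178658076674	0.130374703100478	17.8546313760249	4.35458650839232	1401.72260660819	0	0
psm_00023	spec_00023	NA	0	0.547174008205826	0.156364767652442	23.4436659296	6.81576839154203	1393.43519522953	0	0
psm_00024	spec_00024	NA	0	3.11924228508125	0.120380540613303	6.65571692750462	3.15629694905757	1734.28022231005	0	0
psm_00025	spec_00025	NA	1	1.8433861274029	0.214291458425776	21.5310209428121	2.82673120572677	1682.60105153563	0	0
psm_00026	spec_00026	NA	1	3.51727545117779	0.0607076607892803	22.6589885923943	4.22917208845467	1822.85370524204	0	0
psm_00027	spec_00027	NA	1	3.35785007451359	0.151037861212104	13.1572818150768	3.82378179095132	1819.66729569396	0	0
psm_00028	spec_00028	NA	1	1.85233125353337	0.051599537217368	16.484728689136	2.93989411476603	2148.49392384878	0	0
psm_00029	spec_00029	NA	1	2.38079534559765	0.268714379485952	3.3060364382424	7.62752102039245	1521.13694461569	1	0
psm_00030	spec_00030	NA	1	3.35306608785567	0.168138927239308	14.3442397006777	3.55682604187252	739.432434122048	0	0
psm_00031	spec_00031	NA	1	1.32392977428938	0.0959642245873722	9.27926163401131	5.20507277260429	1337.59975658298	0	0
psm_00032	spec_00032	NA	1	1.9497528230513	0.174961863087176	11.1729292309578	5.41107467844754	1267.21812793766	0	0
psm_00033	spec_00033	NA	1	1.57074878271245	0.0391095777460638	14.7608328128641	-0.576305556611746	1411.21337452807	0	0
psm_00034	spec_00034	NA	1	2.09950412349412	0.225624144247489	17.1666510580175	6.03882971408156	1845.41187162701	0	0
psm_00035	spec_00035	NA	1	1.96418953154487	0.0391152687819851	11.7691059760823	9.50490145984078	1329.33363974055	1	0
psm_00036	spec_00036	NA	1	2.8481343745662	0.0110231732855321	25.1935365629789	4.9587856390118	1258.26409799249	0	0
psm_00037	spec_00037	NA	1	2.33414356565508	0.116132645234351	14.9450287461251	2.67426440746691	1647.77815855249	0	0
psm_00038	spec_00038	NA	1	0.997398243704368	0.17944352138919	10.9881133288539	8.93347440702859	1710.22750119967	0	0
psm_00039	spec_00039	NA	1	2.31952797932166	0.119223229424744	14.2078006900119	5.78157366966453	1427.06241253497	0	0
psm_00040	spec_00040	NA	1	1.05758497704776	0.0667780317753497	11.4987114895858	8.04205102287726	1623.74435307674	0	0
psm_00041	spec_00041	NA	1	0.758471528138902	0.202305947617337	6.53298004004446	5.64678262542396	1649.44959280764	0	0
psm_00042	spec_00042	NA	1	2.50019889660559	0.289011479632433	14.5162366929132	6.84021387827596	1610.30373438691	2	0
psm_00043	spec_00043	NA	1	0.71620039262424	-0.0170958937758292	16.7462004555882	9.33796544318608	1328.81913924309	0	0
psm_00044	spec_00044	NA	1	2.07604269193291	0.223151292540086	13.9140102801116	6.97425770223554	1721.64495531431	0	0
psm_00045	spec_00045	NA	1	1.04970731342215	0.0867581226950889	13.8578910544903	6.12570348947447	819.512602300516	0	0
psm_00046	spec_00046	NA	1	3.07632704715337	0.188681968865011	12.7860820082571	2.97593517218546	1684.21231201574	0	0
psm_00047	spec_00047	NA	1	2.44060750606565	-0.00770486536755927	16.2396994498769	6.74144171988882	1621.09074179998	0	0
psm_00048	spec_00048	NA	1	1.43775204942386	0.101757242785341	5.58303671747412	3.75731200332016	2115.47379800979	0	0
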