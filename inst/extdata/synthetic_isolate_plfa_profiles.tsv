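plfa	Genus01	Genus02	Genus03	Genus04	Genus05	Genus06	Genus07	Genus08	Genus09	Genus10	Genus11	Genus12	Genus13	Genus14	Genus15	Genus16	Genus17	Genus18	Genus19	Genus20	Genus21	Genus22	Genus23	Genus24
14:0	0.0338378	0.138096	0.150779	0.00235695	0.0211934	0.130959	0.00978199	0.0406829	0.0018704	0.0264537	0.0396358	0.10545	0.00671628	0.14615	0.0108546	0.186052	0.301633	0.000927952	0.237711	0.210595	0.0359415	0.0703358	0.19903	0.0164658
i15:0	0.057185	0.0216298	0.0074559	0.0372527	0.0778645	0.0761415	0.0425071	0.0255856	0.054595	0.0773396	0.0585042	0.143372	0.0773598	0.0109828	0.165374	0.0376073	0.0162423	0.057328	0.055444	0.0320543	0.00954341	0.016947	0.0539182	0.047982
a15:0	0.028251	0.201955	0.187763	0.245844	0.0472368	0.00610468	0.0920893	0.0295881	0.00273842	0.283679	0.00156775	0.119814	0.00452055	0.015479	0.121461	0.102357	0.0336666	0.142417	0.00139901	0.0370986	0.0173131	0.00779981	0.0997094	0.0566168
15:0	0.00197343	0.196245	0.00643104	0.0212538	0.0735103	0.0831376	0.164724	0.0633417	0.238115	0.0338761	0.0211467	0.059546	0.0956752	0.0222943	0.0654941	0.0492556	0.0219964	0.0690476	0.0211717	0.0460817	0.0340907	0.1563	0.0854582	0.00798076
i16:0	0.0019067	0.00522782	0.0963556	0.00693077	0.133628	0.0386164	0.308466	0.166277	0.0417914	0.269444	0.0680427	0.0633204	0.031232	0.0621029	0.0187187	0.0458415	0.00785652	0.00609501	0.0696117	0.0931694	0.0298919	0.079924	0.0199724	0.0266497
16:0	0.366647	0.0112498	0.00513593	0.139098	0.0998702	0.00998227	0.000265844	0.0624155	0.00908932	0.0285457	0.00407414	0.0908084	0.056229	0.160459	0.0192965	0.12119	0.00324156	0.031131	0.0456355	0.203864	0.0202195	0.00160215	0.0713349	0.108246
16:1w7	0.0176016	0.00120036	0.0530864	0.0690558	0.0238773	0.087198	0.120429	0.155401	0.107915	0.000689582	0.00470724	0.0187262	0.0722704	0.0137059	0.187842	0.0294761	0.309002	0.472727	0.0637228	0.0799212	0.0187256	0.221506	0.0294418	0.0223079
10Me16:0	0.0505704	0.0045672	0.0654478	0.0885117	0.097176	0.228996	0.0333135	0.0456682	0.000263711	8.48075e-07	0.0145719	0.019247	0.191659	0.0184616	0.00936161	0.250364	0.00732386	0.0140566	0.119644	0.00202114	0.135225	0.0109922	0.0077865	0.18242
a17:0	0.0251831	0.00634999	0.158294	0.031323	0.0563456	0.0551838	0.00937584	0.0488394	0.0721073	0.106746	0.119635	0.00618326	0.0255047	0.107788	0.0296131	0.000527266	0.00159157	0.0615053	0.0496811	0.00467906	0.059587	0.0614236	0.0928255	0.0383314
cy17:0	0.0823315	0.000354807	0.0164545	0.0489708	0.0877731	0.0129989	0.0115081	0.136719	0.032864	0.0908538	0.225826	0.0255462	0.0761174	0.0356311	0.050172	0.0714237	0.00161885	0.0230578	0.038899	0.0266563	0.0590013	0.0482908	0.0405101	0.111648
17:1w8	0.0392263	0.0136212	0.0351291	0.0046541	0.202449	0.0935609	0.0684814	0.0938167	0.196162	0.0223774	0.0460366	0.113618	0.00129624	0.0568088	0.0130228	0.00940586	0.0677135	0.0050233	0.0240901	0.123847	0.0878981	0.0200485	0.04646	0.0403512
18:0	0.0379669	0.141214	0.164214	0.0984323	0.00584126	0.106734	0.0119421	0.101302	0.100371	0.0300152	0.127409	0.0829066	0.056318	0.101762	0.0536801	0.00298936	0.0313716	0.00670308	0.0484933	0.0302248	0.00830313	0.105096	0.0294246	0.189265
18:1w7	0.178493	0.0859629	0.00998827	0.152149	0.0191551	0.0493493	0.0309925	0.0147114	0.100838	0.0145869	0.163324	0.099003	0.00271879	0.0269226	0.0116098	0.0790191	0.0503687	0.0115077	0.0776343	0.0655136	0.472641	0.0879136	0.149447	0.0328067
18:1w9	0.0788267	0.172326	0.0434657	0.0541675	0.0540802	0.0210385	0.0961232	0.0156516	0.041279	0.0153923	0.105519	0.0524583	0.302383	0.221452	0.243499	0.0144915	0.146374	0.0984722	0.146863	0.0442742	0.0116189	0.111821	0.074682	0.118928
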