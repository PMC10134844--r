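taxon_id	g	m_P	m_V	p0
ASV001	0.115837903270749	0.0505230929834931	0.0563641606978507	0.0026431592901184
ASV002	0.151366576561193	0.0655449020107194	0.0459347158881298	0.00080523837677571
ASV003	0.0705108912340285	0.0202234165970594	0.030758631883425	0.0110388712102683
ASV004	0.157748954418219	0.065938431663624	0.0559555313107994	0.0109313817616064
ASV005	0.0682357274678532	0.013847743541998	0.0240671938856117	0.000370167306829319
ASV006	0.108340586352031	0.0577146272796258	0.0327667979065019	0.00840228105629559
ASV007	0.0236430145001328	0.0233413262341667	0.0138753330272161	0.159617222965371
ASV008	0	0	0.00151062203556597	0.00399497065349519
ASV009	0.1051468236577	0.0339826563097566	0.0363497107675864	0.00207756010359722
ASV010	0.145867093674716	0.0618068521974776	0.0435398585652677	0.0389130332568587
ASV011	0.0892521181801073	0.0334213733645685	0.058360119502916	0.0206711653990888
ASV012	0.0454771419266873	0.0195884015973257	0.0212235392235422	0.014840030084158
ASV013	0.172494319971184	0.0814073563193852	0.0792819609887111	0.00355039868072493
ASV014	0.0715259288496298	0.0224908793530568	0.0157272787619768	0.0155482805461591
ASV015	0.0704535479333745	0.0499660947939198	0.0168507847863719	0.00258816361140756
ASV016	0.118413842272571	0.0401470020521162	0.0515427329780206	0.0789097721167503
ASV017	0.107298520643647	0.0569154771635943	0.0365688246982832	0.00767022046869213
ASV018	0.0515738795779745	0.0299272295284197	0.0201940882928573	0.00648404530841672
ASV019	0	0	0	0.00453268112087262
ASV020	0.0710963108650559	0.0190704414094427	0.0264014588977882	0.00353970903374175
ASV021	0.250981889239514	0.103271012806779	0.107789724673185	0.0207574436784277
ASV022	0.0740913638262448	0.0208920069912724	0.0447813855436927	0.00165111135279488
ASV023	0.155412176997787	0.061944206834685	0.0600625435468181	0.0271616964608992
ASV024	0.140192398728754	0.0690780726634745	0.0719687745228717	0.0469556540565521
ASV025	0.138601603896049	0.0648574439626059	0.0685544727232821	0.00171655382069481
ASV026	0.111149550003923	0.0395475090055817	0.0572853693809786	0.0778907567361855
ASV027	0.124448807110984	0.0623212403136254	0.0448927426978573	0.0534108241240415
ASV028	0.0957024045419058	0.0386315314273409	0.0492896718996456	0.0223389028306613
ASV029	0.0997268186600056	0.0314058897381545	0.0497681810803263	0.0458871874049157
ASV030	0.0898286982714129	0.0202294172006034	0.0375559382829703	0.00248325063459874
ASV031	0.0785417670698062	0.0418938256584043	0.0287649786589509	0.00200154301877549
ASV032	0.20178033572664	0.0901470324900815	0.0665878558588816	0.0983127207878462
ASV033	0.0840866591743375	0.0270862429661758	0.0214031534057122	0.00174735226620609
ASV034	0.181829646978565	0.0698706014388937	0.0691123790225128	0.0433991508997216
ASV035	0.0985375424200503	0.0447013749199169	0.0480034400655386	0.0293857691896232
ASV036	0.154204162517768	0.0519098982200933	0.0650741930753429	0.00809406096461567
ASV037	0.245382554363524	0.0995318373865415	0.104290515619249	0.0983639650066507
ASV038	0.115328487826761	0.0251546426014578	0.0357857648856964	0.00277347109506878
ASV039	0.105202266113401	0.0561858014333903	0.0399562318419094	0.0128325371917054
ASV040	0.181085601559074	0.0750225840411114	0.0651588730976755	0.00570769612878767
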