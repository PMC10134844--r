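taxon_id	order
ASV001	Flavobacteriales
ASV002	Alteromonadales
ASV003	Flavobacteriales
ASV004	Rhodobacterales
ASV005	Cellvibrionales
ASV006	Pelagibacterales
ASV007	Synechococcales
ASV008	Rhodobacterales
ASV009	Pelagibacterales
ASV010	Pelagibacterales
ASV011	Flavobacteriales
ASV012	Cellvibrionales
ASV013	Cellvibrionales
ASV014	Rhodobacterales
ASV015	Synechococcales
ASV016	Synechococcales
ASV017	Rhodobacterales
ASV018	Flavobacteriales
ASV019	Cellvibrionales
ASV020	Cellvibrionales
ASV021	Flavobacteriales
ASV022	Flavobacteriales
ASV023	Synechococcales
ASV024	Cellvibrionales
ASV025	Cellvibrionales
ASV026	Rhodobacterales
ASV027	Rhodobacterales
ASV028	Synechococcales
ASV029	Flavobacteriales
ASV030	Alteromonadales
ASV031	Flavobacteriales
ASV032	Alteromonadales
ASV033	Pelagibacterales
ASV034	Synechococcales
ASV035	Rhodobacterales
ASV036	Rhodobacterales
ASV037	Synechococcales
ASV038	Alteromonadales
ASV039	Alteromonadales
ASV040	Alteromonadales
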