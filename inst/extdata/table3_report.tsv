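genome_id	taxon	genome_size_nt	nonamer	genotype	rep_pi_pct	genome_pi_pct	rep_intron	nonamer_apex
Arboreal ant associated circular virus 1	Circoviridae	1769	TAGTATTAC	II	73	67	TRUE	TRUE
Fly associated circular virus 1	Circoviridae	1722	TAGTATTAC	II	89	85	FALSE	TRUE
Soft spider associated circular virus 1	Circoviridae	1937	TAGTATTAC	II	63	59	TRUE	TRUE
Spinybacked orbweaver circular virus 2	Circoviridae	1707	TAGTATTAC	II	99	99	TRUE	TRUE
Cybaeus spider associated circular virus 1	Circularisvirus	1991	TAATACTAC	V	61	60	FALSE	TRUE
Golden silk orbweaver associated circular virus 1	Circularisvirus	2054	CAGTATTAC	V	63	60	FALSE	TRUE
Longjawed orbweaver circular virus 1	Circularisvirus	1905	CATTATTAC	V	60	62	FALSE	TRUE
Spinybacked orbweaver circular virus 1	Circularisvirus	1995	CAGTATTAC	V	63	64	FALSE	TRUE
Fire ant associated circular virus 1	Crucivirus	3226	TATGTGTAA	IV	61	55	FALSE	TRUE
Bark beetle associated circular virus 1	Genomoviridae	2237	TAATATTAT	II	96	92	TRUE	TRUE
Cybaeus spider associated circular virus 2	Genomoviridae	2344	TAATATTAT	II	67	61	TRUE	TRUE
Fly associated circular virus 2	Genomoviridae	2207	TAACATTGT	II	99	99	TRUE	TRUE
Giant house spider associated circular virus 1	Genomoviridae	2093	TAATATTAT	II	73	67	TRUE	TRUE
Grasshopper associated circular virus 1	Genomoviridae	2309	TAACACTGT	II	62	64	TRUE	TRUE
Pimoid spider associated circular molecule 1	Genomoviridae	1662	TAATGTTAT	II	69	68	TRUE	TRUE
Pimoid spider associated circular virus 1	Genomoviridae	2240	TAATATTAT	II	100	99	TRUE	TRUE
Sierra dome spider associated circular virus 1	Genomoviridae	2232	TAATATTAT	II	67	64	TRUE	TRUE
Spider associated circular virus 1	Genomoviridae	2216	TAATACTAT	II	84	74	TRUE	TRUE
Spider associated circular virus 2	Genomoviridae	2204	TAATACTAT	II	85	71	TRUE	TRUE
Termite associated circular virus 2	Genomoviridae	2226	TAATATTAT	II	74	68	TRUE	TRUE
Tubeweb spider associated circular virus 1	Genomoviridae	2174	TAACACTGT	II	63	61	TRUE	TRUE
Fly associated circular virus 3	Smacoviridae	2537	TAGTGTTAC	IV	83	89	FALSE	TRUE
Fly associated circular virus 4	Smacoviridae	2546	TAGTGTTAC	IV	57	61	FALSE	TRUE
Cricket associated circular virus 1	Volvovirus	2516	TAGTATTAC	II	100	99	FALSE	TRUE
Common house spider circular molecule 1	Unclassified	1833	TATTATTAC	V	62	63	FALSE	FALSE
Cybaeus spider associated circular molecule 1	Unclassified	1989	TAGCACTAA	VIII	58	n/a	TRUE	TRUE
False black widow spider associated circular virus 1	Unclassified	2199	TAGTATTAC	I	61	62	FALSE	TRUE
Fly associated circular virus 5	Unclassified	1997	TAGTATTAC	II	97	93	FALSE	TRUE
Fly associated circular virus 6	Unclassified	2103	TAGTATTAC	IV	61	59	FALSE	TRUE
Fly associated circular virus 7	Unclassified	2010	TAGTATTAC	IV	65	66	FALSE	TRUE
Giant house spider associated circular virus 2	Unclassified	2040	TAGTATTAC	V	68	64	FALSE	TRUE
Giant house spider associated circular virus 3	Unclassified	2290	TATTATTAC	I	61	59	FALSE	TRUE
Giant house spider associated circular virus 4	Unclassified	2494	TAATATTAC	IV	62	60	FALSE	TRUE
Longjawed orbweaver circular virus 2	Unclassified	2321	CAGTATTAC	VI	58	57	FALSE	TRUE
Millipede associated circular virus 1	Unclassified	1987	TAGTATTAC	II	59	58	FALSE	TRUE
Pimoid spider associated circular virus 2	Unclassified	2125	TAGTATTAC	I	62	60	FALSE	TRUE
Sierra dome spider associated circular virus 2	Unclassified	1860	TAGTATTAC	V	57	57	FALSE	TRUE
Spider associated circular virus 3	Unclassified	1889	CAACCACTC	I	57	57	FALSE	TRUE
Tentweb spider associated circular virus 1	Unclassified	2127	TAGTATTAC	II	62	60	FALSE	TRUE
Termite associated circular virus 1	Unclassified	2155	TAATATTAC	II	61	55	TRUE	TRUE
Termite associated circular virus 3	Unclassified	2220	TAATGTTAC	II	57	56	TRUE	TRUE
Termite associated circular virus 4	Unclassified	2152	TAATGTTAC	II	58	57	TRUE	TRUE
Water beetle associated circular virus 1	Unclassified	2244	CAGTATTAC	II	56	57	FALSE	TRUE
Woodlouse hunter spider associated circular virus 1	Unclassified	2176	TAATAGTAG	II	57	58	TRUE	TRUE
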