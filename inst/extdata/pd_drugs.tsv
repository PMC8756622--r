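name	struct_id	pubchem_cid	in_lincs	atc_codes
amantadine	144	2130	TRUE	N04BB01
apomorphine	228	6005	TRUE	N04BC07
benzatropine	333	1201549	TRUE	N04AC01
biperiden	374	2381	TRUE	N04AA02
bromocriptine	403	31101	TRUE	N04BC01
dexetimide	831	30843	FALSE	N04AA08
entacapone	1018	5281081	TRUE	N04BX02
levodopa	1567	6047	TRUE	N04BA01
melevodopa	1673	23497	FALSE	N04BA04
metixene	1780	4167	TRUE	N04AA03
opicapone	5143	135565903	FALSE	N04BX04
orphenadrine	1999	4601	TRUE	N04AB02
pergolide	2105	47811	TRUE	N04BC02
pimavanserin	5142	10071196	TRUE	N05AX17
piribedil	2202	4850	TRUE	N04BC08
pramipexole	2233	119570	TRUE	N04BC05
procyclidine	2276	4919	TRUE	N04AA04
rasagiline	3521	3052776	TRUE	N04BD02
rivastigmine	2392	77991	TRUE	N06DA03
ropinirole	2402	5095	TRUE	N04BC04
rotigotine	2407	59227	TRUE	N04BC09
safinamide	4921	131682	TRUE	N04BD03
selegiline	2429	26757	TRUE	N04BD01
tolcapone	2697	4659569	TRUE	N04BX01
trihexyphenidyl	2745	5572	TRUE	N04AA01
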