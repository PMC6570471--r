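sample	gene	label	kind
S01	GENE1	E20K	missense
S02	GENE1	E70K	missense
S03	GENE1	E20K	missense
S04	GENE1	E120A	missense
S05	GENE1	D285E	missense
S06	GENE1	K286E	missense
S07	GENE1	Frameshift at G488	frameshift
S08	GENE2	R12Q	missense
S09	GENE2	G44D	missense
S10	GENE2	E9K	missense
S11	GENE2	T21M	missense
S12	GENE3	L5F	missense
S13	GENE3	P30S	missense
S14	GENE3	A17V	missense
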