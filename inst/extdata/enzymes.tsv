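# plasmidkit enzyme database, format v1
# name <TAB> recognition <TAB> top_cut <TAB> bottom_cut <TAB> methylation <TAB> groups
# cut offsets are inter-base positions from the 5' start of the top-strand
# recognition match; methylation rules are methylase:pattern@offset and a
# site is suppressed when any rule's pattern matches at that offset.
EcoRI	GAATTC	1	5	-	common
HindIII	AAGCTT	1	5	-	common
BamHI	GGATCC	1	5	-	common
XbaI	TCTAGA	1	5	dam:GATC@-2;dam:GATC@4	common
SalI	GTCGAC	1	5	-	common
XhoI	CTCGAG	1	5	-	common
ApaLI	GTGCAC	1	5	-	common
ClaI	ATCGAT	2	4	dam:GATC@-1;dam:GATC@3	common
PstI	CTGCAG	5	1	-	common
KpnI	GGTACC	5	1	-	common
SacI	GAGCTC	5	1	-	common
SmaI	CCCGGG	3	3	-	common,blunt
EcoRV	GATATC	3	3	-	common,blunt
AluI	AGCT	2	2	-	blunt,frequent
MboI	GATC	0	4	dam:GATC@0	frequent
HinfI	GANTC	1	4	-	degenerate,frequent
ScrFI	CCNGG	2	3	dcm:CCWGG@0	degenerate,frequent
NotI	GCGGCCGC	2	6	-	rare
BsaI	GGTCTC	7	11	-	typeIIS
SapI	GCTCTTC	8	11	-	typeIIS
BbsI	GAAGAC	8	12	-	typeIIS
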