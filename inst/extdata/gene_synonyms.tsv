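canonical	category	synonyms
ND1	PCG	NADH1|NAD1|nad1|MT-ND1|NADH dehydrogenase subunit 1
ND2	PCG	NADH2|NAD2|nad2|MT-ND2|NADH dehydrogenase subunit 2
ND3	PCG	NADH3|NAD3|nad3|MT-ND3|NADH dehydrogenase subunit 3
ND4	PCG	NADH4|NAD4|nad4|MT-ND4|NADH dehydrogenase subunit 4
ND4L	PCG	NADH4L|NAD4L|nad4l|MT-ND4L|NADH dehydrogenase subunit 4L
ND5	PCG	NADH5|NAD5|nad5|MT-ND5|NADH dehydrogenase subunit 5
ND6	PCG	NADH6|NAD6|nad6|MT-ND6|NADH dehydrogenase subunit 6
COX1	PCG	COI|COXI|cox1|CO1|MT-CO1|cytochrome c oxidase subunit I|cytochrome c oxidase subunit 1
COX2	PCG	COII|COXII|cox2|CO2|MT-CO2|cytochrome c oxidase subunit II|cytochrome c oxidase subunit 2
COX3	PCG	COIII|COXIII|cox3|CO3|MT-CO3|cytochrome c oxidase subunit III|cytochrome c oxidase subunit 3
ATP6	PCG	ATPase6|atp6|MT-ATP6|ATP synthase F0 subunit 6
ATP8	PCG	ATPase8|atp8|MT-ATP8|ATP synthase F0 subunit 8
CYTB	PCG	CYB|Cytb|cob|cytb|MT-CYB|cytochrome b
12S	rRNA	12S rRNA|12S RNA|12S ribosomal RNA|rrnS|s-rRNA|small subunit ribosomal RNA
16S	rRNA	16S rRNA|16S RNA|16S ribosomal RNA|rrnL|l-rRNA|large subunit ribosomal RNA
tRNA-Leu1	tRNA	trnL1|tRNA-Leu(CUN)|tRNA-Leu 1
tRNA-Leu2	tRNA	trnL2|tRNA-Leu(UUR)|tRNA-Leu 2
tRNA-Ser1	tRNA	trnS1|tRNA-Ser(AGY)|tRNA-Ser 1
tRNA-Ser2	tRNA	trnS2|tRNA-Ser(UCN)|tRNA-Ser 2
tRNA-Met1	tRNA	trnM1|tRNA-Met 1
tRNA-Met2	tRNA	trnM2|tRNA-Met 2
tRNA-Met	tRNA	trnM|tRNA-Met
tRNA-Phe	tRNA	trnF
tRNA-Val	tRNA	trnV
tRNA-Ile	tRNA	trnI
tRNA-Gln	tRNA	trnQ
tRNA-Trp	tRNA	trnW
tRNA-Ala	tRNA	trnA
tRNA-Asn	tRNA	trnN
tRNA-Cys	tRNA	trnC
tRNA-Tyr	tRNA	trnY
tRNA-Asp	tRNA	trnD
tRNA-Lys	tRNA	trnK
tRNA-Gly	tRNA	trnG
tRNA-Arg	tRNA	trnR
tRNA-His	tRNA	trnH
tRNA-Glu	tRNA	trnE
tRNA-Thr	tRNA	trnT
tRNA-Pro	tRNA	trnP
OL	origin	O_L|OL origin|rep_origin|L-strand origin|origin of L-strand replication
CR	control_region	D-loop|control region|Control region|d-loop|putative control region
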