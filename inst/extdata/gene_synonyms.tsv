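# Synonym table v1: raw annotation label -> canonical symbol.
# Matching is case-insensitive after removing spaces, hyphens and underscores.
raw	canonical
COI	COX1
CO1	COX1
COXI	COX1
COX1	COX1
cytochrome c oxidase subunit I	COX1
cytochrome c oxidase subunit 1	COX1
COII	COX2
CO2	COX2
COXII	COX2
COX2	COX2
cytochrome c oxidase subunit II	COX2
cytochrome c oxidase subunit 2	COX2
COIII	COX3
CO3	COX3
COXIII	COX3
COX3	COX3
cytochrome c oxidase subunit III	COX3
cytochrome c oxidase subunit 3	COX3
COB	CYTB
CYB	CYTB
CYTB	CYTB
cytochrome b	CYTB
ATPase6	ATP6
ATPase 6	ATP6
ATP synthase F0 subunit 6	ATP6
ATP6	ATP6
ATPase8	ATP8
ATPase 8	ATP8
ATP synthase F0 subunit 8	ATP8
ATP8	ATP8
ATP9	ATP9
ATP synthase F0 subunit 9	ATP9
NAD1	ND1
NADH1	ND1
ND1	ND1
NADH dehydrogenase subunit 1	ND1
NAD2	ND2
NADH2	ND2
ND2	ND2
NADH dehydrogenase subunit 2	ND2
NAD3	ND3
NADH3	ND3
ND3	ND3
NADH dehydrogenase subunit 3	ND3
NAD4	ND4
NADH4	ND4
ND4	ND4
NADH dehydrogenase subunit 4	ND4
NAD4L	ND4L
NADH4L	ND4L
ND4L	ND4L
NADH dehydrogenase subunit 4L	ND4L
NAD5	ND5
NADH5	ND5
ND5	ND5
NADH dehydrogenase subunit 5	ND5
NAD6	ND6
NADH6	ND6
ND6	ND6
NADH dehydrogenase subunit 6	ND6
12S	rrnS
12S rRNA	rrnS
12S ribosomal RNA	rrnS
s-rRNA	rrnS
small subunit ribosomal RNA	rrnS
rrn12	rrnS
rrnS	rrnS
16S	rrnL
16S rRNA	rrnL
16S ribosomal RNA	rrnL
l-rRNA	rrnL
large subunit ribosomal RNA	rrnL
rrn16	rrnL
rrnL	rrnL
tRNA-Ala	trnA
tRNA-Arg	trnR
tRNA-Asn	trnN
tRNA-Asp	trnD
tRNA-Cys	trnC
tRNA-Gln	trnQ
tRNA-Glu	trnE
tRNA-Gly	trnG
tRNA-His	trnH
tRNA-Ile	trnI
tRNA-Leu	trnL
tRNA-Lys	trnK
tRNA-Met	trnM
tRNA-Phe	trnF
tRNA-Pro	trnP
tRNA-Ser	trnS
tRNA-Thr	trnT
tRNA-Trp	trnW
tRNA-Tyr	trnY
tRNA-Val	trnV
trnA	trnA
trnR	trnR
trnN	trnN
trnD	trnD
trnC	trnC
trnQ	trnQ
trnE	trnE
trnG	trnG
trnH	trnH
trnI	trnI
trnL	trnL
trnL1	trnL1
trnL2	trnL2
trnK	trnK
trnM	trnM
trnF	trnF
trnP	trnP
trnS	trnS
trnS1	trnS1
trnS2	trnS2
trnT	trnT
trnW	trnW
trnY	trnY
trnV	trnV
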