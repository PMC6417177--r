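# Illustrative vitamin catalog: a small hand-picked subset of KO and EC
# identifiers per vitamin, sufficient to exercise the pipeline. Supply a
# curated catalog for production analyses.
vitamin	category	id_type	identifier
BIO	biosynthesis	KO	K00652
BIO	biosynthesis	KO	K00833
BIO	biosynthesis	KO	K01935
BIO	biosynthesis	KO	K01012
BIO	transport	KO	K03523
COB	biosynthesis	KO	K00798
COB	biosynthesis	KO	K02232
COB	biosynthesis	KO	K02227
COB	transport	KO	K16092
COB	transport	KO	K06858
FOL	biosynthesis	KO	K01495
FOL	biosynthesis	KO	K00287
FOL	biosynthesis	KO	K11754
FOL	transport	KO	K16923
MEN	biosynthesis	KO	K02548
MEN	biosynthesis	KO	K01661
MEN	biosynthesis	KO	K02552
NIA	biosynthesis	KO	K03517
NIA	biosynthesis	KO	K00278
NIA	biosynthesis	KO	K00767
NIA	transport	KO	K03811
PAN	biosynthesis	KO	K00606
PAN	biosynthesis	KO	K01918
PAN	biosynthesis	KO	K00077
PAN	transport	KO	K14392
PYR	biosynthesis	KO	K03474
PYR	biosynthesis	KO	K03473
PYR	biosynthesis	KO	K00275
RIB	biosynthesis	KO	K00793
RIB	biosynthesis	KO	K00794
RIB	biosynthesis	KO	K02858
THI	biosynthesis	KO	K03147
THI	biosynthesis	KO	K00788
THI	biosynthesis	KO	K00878
THI	biosynthesis	KO	K00941
THI	transport	KO	K02064
BIO	biosynthetic	EC	2.8.1.6
COB	biosynthetic	EC	6.3.5.10
FOL	biosynthetic	EC	6.3.2.17
FOL	biosynthetic	EC	3.5.4.16
MEN	biosynthetic	EC	4.1.3.36
NIA	biosynthetic	EC	2.4.2.19
PAN	biosynthetic	EC	6.3.2.1
PYR	biosynthetic	EC	1.4.3.5
RIB	biosynthetic	EC	2.5.1.9
THI	biosynthetic	EC	2.5.1.3
BIO	dependent	EC	6.4.1.1
BIO	dependent	EC	6.4.1.2
COB	dependent	EC	5.4.99.2
COB	dependent	EC	2.1.1.13
FOL	dependent	EC	2.1.2.1
MEN	dependent	EC	1.3.5.4
NIA	dependent	EC	1.1.1.27
PAN	dependent	EC	2.3.1.12
PYR	dependent	EC	2.6.1.1
RIB	dependent	EC	1.3.5.1
THI	dependent	EC	1.2.4.1
THI	dependent	EC	2.2.1.1
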