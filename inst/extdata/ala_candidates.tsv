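# Worked-example candidate table: four alpha-lactalbumin-derived peptides plus
# a bovine milk-derived positive-control ACP (BMP-S6), with secondary-structure
# labels and ACP probabilities from three external classifiers
# (ACPred-FL, AntiCP2.0, mACPpred). role: candidate peptides are screened;
# controls bypass filters and are excluded from the shortlist.
peptide_id	sequence	structure_label	acpred_fl	anticp2	macppred	role
ALA-A1	RFFVPLFLVGILFPAILAKQFTK	coil-helix-coil-helix	0.980	0.620	0.964	candidate
ALA-A2	KLWCKSSQVPQSR	helix-coil	0.992	0.480	0.798	candidate
ALA-A3	RFFVPLFLVGILFPAILAKQFTKC	helix-coil-helix	0.980	0.590	0.977	candidate
ALA-A4	LFQISNKLWCKSSQVPQSRN	coil	0.944	0.460	0.075	candidate
BMP-S6	FKCRRWQWRMKKLGAPSITCVR	coil-helix	0.606	1.000	0.9848	control
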