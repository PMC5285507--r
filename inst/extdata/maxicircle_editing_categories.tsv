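transcript_id	category	u_insertions	u_deletions
RPS12	pan_edited	NA	NA
ND3	pan_edited	NA	NA
CR4	pan_edited	NA	NA
ND8	pan_edited	NA	NA
ND9	pan_edited	NA	NA
CR3	pan_edited	NA	NA
A6	pan_edited	NA	NA
ND7	pan_edited	NA	NA
COX3	pan_edited	NA	NA
COX2	minimally_edited	4	0
MURF2	minimally_edited	26	4
CYB	minimally_edited	39	0
ND1	never_edited	0	0
COX1	never_edited	0	0
ND4	never_edited	0	0
ND5	never_edited	0	0
MURF5	never_edited	0	0
MURF1	never_edited	0	0
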