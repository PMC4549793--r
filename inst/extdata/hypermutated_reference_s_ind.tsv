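# Published reference set: TCGA colorectal/endometrial/gastric tumors that
# are hypermutated (T.sns > 60/Mb) and/or had discordant MSI status between
# the sequence-based classifier and laboratory testing. s_ind_per_mb values
# are as published; exact substitution burdens were not published for these
# samples, so t_sns_per_mb records a representative value on the correct
# side of the 60/Mb hypermutation condition (100 for hypermutated rows, 10
# otherwise) — only that condition enters the POLE flag.
sample_id	t_sns_per_mb	s_ind_per_mb	hypermutated	lab_msi_h	published_msih_call
TCGA-F5-6814	100	0.045	TRUE	N	N
TCGA-CA-6717	100	0.11	TRUE	N	N
TCGA-AZ-4315	100	0.045	TRUE	N	N
TCGA-EI-6917	100	0.091	TRUE	N	N
TCGA-AA-3510	100	0.023	TRUE	N	N
TCGA-CA-6718	100	0.023	TRUE	N	N
TCGA-AM-5821	100	0.25	TRUE	Y	N
TCGA-AM-5820	100	2.61	TRUE	N	Y
TCGA-A5-A0GD	10	0.00	FALSE	Y	N
TCGA-DC-6154	10	0.045	FALSE	Y	N
TCGA-G4-6304	10	0.27	FALSE	Y	N
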