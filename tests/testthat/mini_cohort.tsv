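# cerebnorm cohort seed=7 age_mean=10.5 age_sd=2.5
subject_id	wave	age	sex	scanner	lobule_v
sub00001	1	7.9	female	MR750	9.25
sub00001	2	10.2	female	MR750w	9.8
sub00002	2	10.4	male	MR750w	11.05
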