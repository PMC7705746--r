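element_id	age_my
ltr_00001	1
ltr_00002	1
ltr_00003	4
ltr_00004	4
ltr_00005	6
ltr_00006	6
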