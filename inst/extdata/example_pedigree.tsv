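role	member_index	affected	age_dx	multiple_polyps	other_cancers	multiple_crc
mother	0	1	52	0	0	0
maternal_grandmother	0	1	49	0	0	0
maternal_aunt_uncle	0	1	47	0	0	0
sibling	0	1	61	0	1	0
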