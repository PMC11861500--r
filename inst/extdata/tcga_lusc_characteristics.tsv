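characteristic	level	ros1_mut	ros1_wt
gender	Male	31	342
gender	Female	13	118
age	>=65	31	294
age	<65	13	157
age	Unknown	0	9
smoking	Yes	38	389
smoking	Unknown	6	71
location	Central	12	135
location	Peripheral	8	85
location	Unknown	24	240
tnm_stage	I	25	188
tnm_stage	II	11	132
tnm_stage	III	7	70
tnm_stage	IV	1	70
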