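variant_id	pos1	pos2	pos3	activity_no_heat	residual_activity
WT	P	L	V	1000	52
P233G/L234E/V235M	G	E	M	1580	560
P233D/L234G/V235G	D	G	G	1350	800
P233D/L234P/V235S	D	P	S	1220	800
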