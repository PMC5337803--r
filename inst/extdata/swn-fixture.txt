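# synthetic SentiWordNet-3.0-format fixture lexicon
# POS	ID	PosScore	NegScore	SynsetTerms	Gloss
a	00230335	0.875	0	better#1	(comparative of good) superior to another in excellence or quality
a	00231567	0.5	0.25	better#2	more than half; a distractor sense
a	00334912	0	0.625	dangerous#1	involving or causing danger or risk
a	00412788	0	0.75	terrible#1	causing fear or dread
a	00518340	0	0.5	sugary#1	containing sugar; cloyingly sweet
a	00612405	0.75	0	great#1	very good
a	00710233	0.625	0	safe#1	free from danger or risk
a	00815627	0.125	0	stable#1	resistant to change; steady
a	00920154	0.5	0	fine#1	being satisfactory or in satisfactory condition
r	00117821	0	0.625	badly#1	to a severe or serious degree
n	04316275	0	0.5	drop#1	a sudden sharp decrease in quantity or degree
n	07516354	0	0.25	alert#1	warning serves to make you more alert to danger
v	01124794	0	0.375	spike#1	to rise sharply
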