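# diabetes jargon abbreviations
hypo	Hypoglycemia
hyper	Hyperglycemia
carbs	carbohydrates
bg	blood glucose
t1d	type 1 diabetes
t2d	type 2 diabetes
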