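# synthetic miniature diabetes-domain gazetteer (concept_id<TAB>term)
DDO:0001	diabetes
DDO:0002	blood sugar
DDO:0003	glucose tablet
DDO:0004	insulin
DDO:0005	hypoglycemia
DDO:0006	carbohydrate
DDO:0007	metformin
DDO:0008	oral hypoglycemic
DDO:0009	hba1c test
DDO:0010	insulin pump
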