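drug_code,sek_per_unit,class
REL_SSRI,3.2,related
REL_SNRI,6.5,related
REL_HYPNOTIC,2.4,related
UNREL_PPI,4.1,unrelated
UNREL_ANALGESIC,1.8,unrelated
UNREL_THYROID,2.9,unrelated
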