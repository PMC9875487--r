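cohort,reference_n,case_n
copdgene_discovery,128,489
copdgene_validation,149,614
mesa_validation,104,327
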