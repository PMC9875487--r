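cohort,cluster,n
copdgene_discovery,0,181
copdgene_discovery,1,156
copdgene_discovery,2,79
copdgene_discovery,3,73
copdgene_validation,0,288
copdgene_validation,1,193
copdgene_validation,2,42
copdgene_validation,3,91
mesa_validation,0,150
mesa_validation,1,64
mesa_validation,2,41
mesa_validation,3,72
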