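species,light,delta_dm_permil,delta_ew_permil
Capsicum_annuum,HL,-28.26,-33.91
Capsicum_annuum,LL,-33.91,-37.41
Brassica_oleracea,HL,-27.63,-37.98
Brassica_oleracea,LL,-33.95,-40.87
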