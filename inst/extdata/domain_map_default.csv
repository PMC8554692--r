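domain,start,end
TAD,1,61
PR,64,92
DNAB,94,312
OD,323,356
CT,364,393
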