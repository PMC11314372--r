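seq_id	cys	his	asp
SYN_PCS_REF1	56	162	180
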