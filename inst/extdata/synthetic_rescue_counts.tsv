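condition	rescued	not_rescued
wildtype_mrna_coinjection	68	17
morpholino_alone	22	63
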