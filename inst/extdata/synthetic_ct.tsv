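group	target_ct	reference_ct
test	26.1	12.0
test	26.4	12.2
test	25.9	11.9
control	24.2	12.1
control	24.0	11.8
control	24.4	12.2
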