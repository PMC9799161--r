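digit,cd_per_m2
21,2.24
145,136
255,450
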