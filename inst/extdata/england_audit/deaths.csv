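"death_band","deaths","role"
"25-39",103,"band"
"40-54",175,"band"
"55-69",199,"band"
"70-84",216,"band"
"25-84",692,"covered"
"all_ages",796,"total"
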