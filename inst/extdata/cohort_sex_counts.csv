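group,male,female
lvPPA,6,7
svPPA,4,7
control,18,16
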