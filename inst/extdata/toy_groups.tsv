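sample_id	label
C1	control
C2	control
C3	control
C4	control
C5	control
E1	experimental
E2	experimental
E3	experimental
E4	experimental
E5	experimental
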