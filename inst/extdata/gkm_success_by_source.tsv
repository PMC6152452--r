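source	success	failure
pole	19	53
tree	29	24
barbed_wire	10	2
hair_trap	3	4
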