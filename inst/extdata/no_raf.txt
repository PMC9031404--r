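# a system with reactions but no catalysis: contains no RAF
F: a, b
r1: a -> c
r2: b + c -> d
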