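# Formation of the distressing belief "I am stupid" (b1C):
# two adverse memories, redescribed under the catalyzing incident mC.
F: GC, PC, mC
r1: GC + PC -> b1C
cat: mC r1
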