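# misinformation subset; entries after the first are reconstructions
change dna
alter your dna
alters your dna
microchip
sterilize
aborted cells
depopulation
genocidal weapon
mark of the beast
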