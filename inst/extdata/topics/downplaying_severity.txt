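# downplaying-severity subset; entries after the first two are reconstructions
lower than flu
mild
overcount
inflated
false positive
exaggerat
comorbidit
just the flu
99 percent survive
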