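# hesitancy subset; entries after the first are reconstructions
will not take
won't take
never take
rushed
adverse reaction
side effect
not getting the vaccine
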