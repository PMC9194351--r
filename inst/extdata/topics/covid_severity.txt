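# severity family; entries below the first three are reconstructions
death rate
fatality rate
confirmed cases
case spike
death count
survival rate
case count
death toll
hospitalization
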