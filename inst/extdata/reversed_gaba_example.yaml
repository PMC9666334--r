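# Reversed (excitatory) GABA variant: chloride-gradient inversion turns the
# TRN projection excitatory; the loop is bistable over the whole range of a.
variant: reversed_gaba
a: 0.5
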