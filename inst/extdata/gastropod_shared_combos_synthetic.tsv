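combo	n
AZO+MAD+SEL+CAN+CAB	3
AZO+MAD+SEL+CAN	10
MAD+SEL+CAN	27
AZO+MAD+CAN	8
MAD+CAN	17
AZO+MAD	20
SEL+CAN	19
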