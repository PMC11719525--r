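ENST00000000101.3	Q12345
ENST00000000301.1	P67890
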