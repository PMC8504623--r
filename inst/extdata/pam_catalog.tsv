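motif	side
NGG	3prime
TTTV	5prime
TTN	5prime
NNAGAAW	3prime
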