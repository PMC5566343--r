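# synthetic reference complexes for the toy network
p01	p02	p03	p04	p05	p06
p07	p08	p09	p10	p11	p12
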