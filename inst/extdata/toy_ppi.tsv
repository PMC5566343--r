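# synthetic toy PPI network: two dense 6-protein blocks joined by one bridge edge
p01	p03
p01	p04
p01	p05
p01	p06
p02	p03
p02	p04
p02	p05
p02	p06
p03	p05
p03	p06
p04	p05
p04	p06
p07	p09
p07	p10
p07	p11
p07	p12
p08	p09
p08	p10
p08	p11
p08	p12
p09	p11
p09	p12
p10	p11
p10	p12
p06	p07
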