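# Kynurenine-pathway gene panel
IDO1
IDO2
TDO2
KMO
KYNU
CCBL1
CCBL2
GOT2
AADAT
ACMSD
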