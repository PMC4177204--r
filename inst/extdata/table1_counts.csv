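source,n_classes
OVAE,626
BFO,40
CHEBI,7
OBI,8
PATO,7
IAO,6
NCBOTaxon,81
OAE,119
OGMS,2
RO,0
UBERON,105
VO,188
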