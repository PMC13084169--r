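category	count	compartment
heparan sulfate degradation intermediates	27	lysosome
dermatan sulfate degradation intermediates	5	lysosome
L-iduronic acid	1	cytosol
L-iduronic acid	1	extracellular
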