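study	n_samples	cancer_type
BRCA_wgs	560	breast
ESOP_wgs	129	oesophageal
PANC_wgs	100	pancreatic
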