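gene	database	sample_size	freq_het_loss	freq_het_loss_east_asia
LRRC40	DGV-like	1000	0.009556907	NA
LRRC40	gnomAD-like	10847	4.61e-05	0.0
SCN7A	DGV-like	1000	0.002257336	NA
SCN7A	gnomAD-like	10847	4.61e-05	0.0
MME	DGV-like	1000	0.000798722	NA
MME	gnomAD-like	10847	4.62e-05	0.0
NAE1	DGV-like	50	0.03	NA
NAE1	gnomAD-like	10847	0.0	0.0
TBX6	DGV-like	1000	0.0005	NA
TBX6	gnomAD-like	10847	0.0001462	0.0
DHX40	DGV-like	1000	9.22e-05	NA
DHX40	gnomAD-like	10847	0.0025	0.008152
GMCL1	DGV-like	1000	0.001303781	NA
GMCL1	gnomAD-like	10847	4.79e-05	0.0
MYSM1	DGV-like	1000	9.22e-05	NA
MYSM1	gnomAD-like	10847	4.61e-05	0.0004139
RASA2	DGV-like	1000	0.00086881	NA
RASA2	gnomAD-like	10847	0.0	0.0
NSMAF	DGV-like	1000	0.001145475	NA
NSMAF	gnomAD-like	10847	0.0	0.0
MNS1	DGV-like	1000	0.00518807	NA
MNS1	gnomAD-like	10847	9.22e-05	0.0
PHKB	DGV-like	1000	0.001198083	NA
PHKB	gnomAD-like	10847	4.81e-05	0.0
SPO11	DGV-like	1000	0.00064226	NA
SPO11	gnomAD-like	10847	0.0	0.0
ABCA6	DGV-like	1000	0.0009219	NA
ABCA6	gnomAD-like	10847	0.0	0.0
ZZZAA	DGV-like	1000	0.0001	NA
ZZZAA	gnomAD-like	10847	0.0	0.0
ZZZBB	DGV-like	1000	0.0001	NA
ZZZBB	gnomAD-like	10847	0.0	0.0
ZZZCC	DGV-like	1000	0.02	NA
ZZZCC	gnomAD-like	10847	0.0	0.0
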