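gene	database	sample_size	freq_het_loss	freq_het_loss_east_asia
NOTCH2	DGV-like	1000	0.0037	NA
NOTCH2	gnomAD-like	10847	0.00037	0.0
DSCAM	DGV-like	1000	0.00049	NA
SNTG1	DGV-like	1000	0.0002	NA
SNTG1	gnomAD-like	10847	4.6e-05	0.0
TBX6	DGV-like	1000	0.0005	NA
TBX6	gnomAD-like	10847	0.0001462	0.0
NBPF20	DGV-like	1000	0.0	NA
NBPF20	gnomAD-like	10847	0.0	0.0
FAM138C	DGV-like	1000	0.0074	NA
DHX40	DGV-like	1000	9.22e-05	NA
DHX40	gnomAD-like	10847	0.0025	0.008152
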