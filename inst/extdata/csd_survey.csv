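metal,donor_context,mean,su,n_hits
RE,imidazole_N,2.185,0.007,NA
RE,carboxylate_O,2.14,0.06,NA
RE,amide_N,2.18,0.01,NA
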