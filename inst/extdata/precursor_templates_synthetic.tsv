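name	loop_sequence	forward_overhang	reverse_overhang	star_overhang	duplex_template	oligo_length
OsMIR390	GCUCGCUUUAAGGCUC	CTTG	CATG	CA	G..................CA	60
OsMIR390-AtL	UAUUCGUUAUCUAUUUUUGGAUUUUCGAUCU	CTTG	CATG	CA	G..................CA	75
AtMIR390a-OsL	GCUCGCUUUAAGGCUC	CTTG	CATG	CA	G..................CA	60
AtMIR390a	UAUUCGUUAUCUAUUUUUGGAUUUUCGAUCU	CTTG	CATG	CA	G..................CA	75
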