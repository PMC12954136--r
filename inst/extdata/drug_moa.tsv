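drug	moa
docetaxel	anti_microtubule
paclitaxel	anti_microtubule
5-fluorouracil	anti_replication
oxaliplatin	anti_replication
irinotecan	anti_replication
epirubicin	anti_replication
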