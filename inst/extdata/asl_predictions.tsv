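endpoint	direction
BA46	up
FrontalMid	up
Hippocampus	up
M1	up
SuperiorParietal	up
Precuneus	up
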