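group	channel
left_temporal	F7
left_temporal	FT7
left_temporal	T7
left_temporal	TP7
left_temporal	P7
left_temporal	P9
left_temporal	F5
left_temporal	FC5
left_temporal	C5
left_temporal	CP5
left_temporal	P5
right_temporal	F8
right_temporal	FT8
right_temporal	T8
right_temporal	TP8
right_temporal	P8
right_temporal	P10
right_temporal	F6
right_temporal	FC6
right_temporal	C6
right_temporal	CP6
right_temporal	P6
frontal	Fp1
frontal	Fpz
frontal	Fp2
frontal	AF7
frontal	AF3
frontal	AFz
frontal	AF4
frontal	AF8
frontal	F3
frontal	F1
frontal	Fz
frontal	F2
frontal	F4
central	FC3
central	FC1
central	FCz
central	FC2
central	FC4
central	C3
central	C1
central	Cz
central	C2
central	C4
parietal	CP3
parietal	CP1
parietal	CPz
parietal	CP2
parietal	CP4
parietal	P3
parietal	P1
parietal	Pz
parietal	P2
parietal	P4
occipital	PO7
occipital	PO3
occipital	POz
occipital	PO4
occipital	PO8
occipital	O1
occipital	Oz
occipital	O2
occipital	Iz
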