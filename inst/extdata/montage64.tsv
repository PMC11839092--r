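channel	x	y
Fp1	-0.2023	0.9
Fpz	0	0.9
Fp2	0.2023	0.9
AF7	-0.5848	0.72
AF3	-0.2924	0.72
AFz	0	0.72
AF4	0.2924	0.72
AF8	0.5848	0.72
F7	-0.8829	0.54
F5	-0.6622	0.54
F3	-0.4414	0.54
F1	-0.2207	0.54
Fz	0	0.54
F2	0.2207	0.54
F4	0.4414	0.54
F6	0.6622	0.54
F8	0.8829	0.54
FT7	-1.045	0.27
FC5	-0.729	0.27
FC3	-0.486	0.27
FC1	-0.243	0.27
FCz	0	0.27
FC2	0.243	0.27
FC4	0.486	0.27
FC6	0.729	0.27
FT8	1.045	0.27
T7	-1.15	0
C5	-0.75	0
C3	-0.5	0
C1	-0.25	0
Cz	0	0
C2	0.25	0
C4	0.5	0
C6	0.75	0
T8	1.15	0
TP7	-1.045	-0.27
CP5	-0.729	-0.27
CP3	-0.486	-0.27
CP1	-0.243	-0.27
CPz	0	-0.27
CP2	0.243	-0.27
CP4	0.486	-0.27
CP6	0.729	-0.27
TP8	1.045	-0.27
P7	-0.8829	-0.54
P5	-0.6622	-0.54
P3	-0.4414	-0.54
P1	-0.2207	-0.54
Pz	0	-0.54
P2	0.2207	-0.54
P4	0.4414	-0.54
P6	0.6622	-0.54
P8	0.8829	-0.54
P9	-0.997	-0.64
P10	0.997	-0.64
PO7	-0.5358	-0.74
PO3	-0.2679	-0.74
POz	0	-0.74
PO4	0.2679	-0.74
PO8	0.5358	-0.74
O1	-0.18	-0.92
Oz	0	-0.92
O2	0.18	-0.92
Iz	0	-1.08
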