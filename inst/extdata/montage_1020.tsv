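name	x	y
Fp1	-0.31	0.95
Fp2	0.31	0.95
F7	-0.81	0.59
F3	-0.4	0.55
Fz	0	0.5
F4	0.4	0.55
F8	0.81	0.59
FC5	-0.69	0.28
FC1	-0.22	0.28
FC2	0.22	0.28
FC6	0.69	0.28
T7	-1	0
C3	-0.5	0
Cz	0	0
C4	0.5	0
T8	1	0
TP9	-1.08	-0.33
CP5	-0.69	-0.28
CP1	-0.22	-0.28
CP2	0.22	-0.28
CP6	0.69	-0.28
TP10	1.08	-0.33
P7	-0.81	-0.59
P3	-0.4	-0.55
Pz	0	-0.5
P4	0.4	-0.55
P8	0.81	-0.59
POz	0	-0.75
O1	-0.31	-0.95
O2	0.31	-0.95
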