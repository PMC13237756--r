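label	theta_deg	phi_deg
AF3	61.828159725424	109.50202638463
AF4	61.828159725424	70.4979736153697
AF7	72	126
AF8	72	54
C1	18	180
C2	18	0
C3	36	180
C4	36	0
C5	54	180
C6	54	0
CP1	26.8229863288272	-128.995292522247
CP2	26.8229863288272	-51.0047074777526
CP3	40.7834337331844	-146.314144605162
CP4	40.7834337331844	-33.6858553948383
CP5	56.1517034917186	-155.622074761554
CP6	56.1517034917186	-24.3779252384463
CPz	18	-90
Cz	0	0
F1	42.2633437591278	109.348256496608
F2	42.2633437591278	70.6517435033919
F3	51.0069818569306	123.85873720573
F4	51.0069818569306	56.1412627942695
F5	61.1327600600232	134.952746075848
F6	61.1327600600232	45.0472539241524
F7	72	144
F8	72	36
FC1	26.8229863288272	128.995292522247
FC2	26.8229863288272	51.0047074777526
FC3	40.7834337331844	146.314144605162
FC4	40.7834337331844	33.6858553948383
FC5	56.1517034917186	155.622074761554
FC6	56.1517034917186	24.3779252384463
FCz	18	90
FT10	90	18
FT7	72	162
FT8	72	18
FT9	90	162
Fp1	72	108
Fp2	72	72
Fz	36	90
O1	72	-108
O2	72	-72
Oz	72	-90
P1	42.2633437591278	-109.348256496608
P2	42.2633437591278	-70.6517435033919
P3	51.0069818569306	-123.85873720573
P4	51.0069818569306	-56.1412627942695
P5	61.1327600600232	-134.952746075848
P6	61.1327600600232	-45.0472539241524
P7	72	-144
P8	72	-36
PO10	90	-54
PO3	61.828159725424	-109.50202638463
PO4	61.828159725424	-70.4979736153697
PO7	72	-126
PO8	72	-54
PO9	90	-126
POz	54	-90
Pz	36	-90
T7	72	180
T8	72	0
TP10	90	-18
TP7	72	-162
TP8	72	-18
TP9	90	-162
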