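label	theta	phi
Fp1	72.9089	108.8623
Fpz	72	90
Fp2	72.9089	71.1377
AFp3h	66.1397	119.7632
AFpz	63	90
AFp4h	66.1397	60.2368
AF7	79.535	165.2721
AF3	61.6062	131.9256
AFz	54	90
AF4	61.6062	48.0744
AF8	79.535	14.7279
AFF7h	71.2754	160.1865
AFF5h	60	144.7356
AFF1h	45.7011	102.6253
AFFz	45	90
AFF2h	45.7011	77.3747
AFF6h	60	35.2644
AFF8h	71.2754	19.8135
F9	90	180
F7	75.5225	169.1877
F5	61.6062	156.875
F3	49.1176	141.0266
F1	39.6981	118.9332
Fz	36	90
F2	39.6981	61.0668
F4	49.1176	38.9734
F6	61.6062	23.125
F8	75.5225	10.8123
F10	90	0
FFC5h	50.9472	155.5824
FFC3h	37.4492	138.2988
FFC1h	28.3532	109.2324
FFC2h	28.3532	70.7676
FFC4h	37.4492	41.7012
FFC6h	50.9472	24.4176
FT9	90	180
FT7	72.9089	174.2664
FC5	56.0122	167.3461
FC3	39.6981	156.9587
FC1	25.2428	136.437
FCz	18	90
FC2	25.2428	43.563
FC4	39.6981	23.0413
FC6	56.0122	12.6539
FT8	72.9089	5.7336
FT10	90	0
FTT7h	63.3589	175.4427
FCC5h	45.7011	171.109
FCC3h	28.3532	162.9325
FCC1h	12.7016	135.3549
FCC2h	12.7016	44.6451
FCC4h	28.3532	17.0675
FCC6h	45.7011	8.891
FTT8h	63.3589	4.5573
T9	90	180
T7	72	180
C5	54	180
C3	36	180
C1	18	180
Cz	0	0
C2	18	0
C4	36	0
C6	54	0
T8	72	0
T10	90	0
TTP7h	63.3589	-175.4427
CCP5h	45.7011	-171.109
CCP3h	28.3532	-162.9325
CCP1h	12.7016	-135.3549
CCP2h	12.7016	-44.6451
CCP4h	28.3532	-17.0675
CCP6h	45.7011	-8.891
TTP8h	63.3589	-4.5573
TP9	90	-180
TP7	72.9089	-174.2664
CP5	56.0122	-167.3461
CP3	39.6981	-156.9587
CP1	25.2428	-136.437
CPz	18	-90
CP2	25.2428	-43.563
CP4	39.6981	-23.0413
CP6	56.0122	-12.6539
TP8	72.9089	-5.7336
TP10	90	0
TPP7h	66.1397	-166.9754
CPP5h	50.9472	-155.5824
CPP3h	37.4492	-138.2988
CPP1h	28.3532	-109.2324
CPP2h	28.3532	-70.7676
CPP4h	37.4492	-41.7012
CPP6h	50.9472	-24.4176
TPP8h	66.1397	-13.0246
P9	90	-180
P7	75.5225	-169.1877
P5	61.6062	-156.875
P3	49.1176	-141.0266
P1	39.6981	-118.9332
Pz	36	-90
P2	39.6981	-61.0668
P4	49.1176	-38.9734
P6	61.6062	-23.125
P8	75.5225	-10.8123
P10	90	0
PPO9h	83.6492	-173.6098
PPO5h	60	-144.7356
PPO1h	45.7011	-102.6253
PPOz	45	-90
PPO2h	45.7011	-77.3747
PPO6h	60	-35.2644
PPO10h	83.6492	-6.3902
PO7	79.535	-165.2721
PO3	61.6062	-131.9256
POz	54	-90
PO4	61.6062	-48.0744
PO8	79.535	-14.7279
POO9h	85.9274	-171.9674
POO1	64.42	-110.0352
POOz	63	-90
POO2	64.42	-69.9648
POO10h	85.9274	-8.0326
O1	72.9089	-108.8623
Oz	72	-90
O2	72.9089	-71.1377
OI1h	81.1117	-99.1103
OI2h	81.1117	-80.8897
Iz	90	-90
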