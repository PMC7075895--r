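# Canonical acoustic feature inventory, version 1 (88 features).
# Descriptor sub-indices: a=median, b=IQR, c=kurtosis, d=skewness,
# e=5th percentile, f=50th percentile, g=95th percentile, h=local, i=frames.
Pitch_a
Pitch_b
Pitch_c
Pitch_d
Pitch_e
Pitch_g
Jitter_h
Jitter_ppq5
Shimmer_h
Shimmer_apq5
VoiceBreaks_n
VoiceBreaks_deg
HNR
NHR
MeanAutocorr
MaxdB
MaxFreq
Energy
Slope
MFCC01_a
MFCC01_b
MFCC02_a
MFCC02_b
MFCC03_a
MFCC03_b
MFCC04_a
MFCC04_b
MFCC05_a
MFCC05_b
MFCC06_a
MFCC06_b
MFCC07_a
MFCC07_b
MFCC08_a
MFCC08_b
MFCC09_a
MFCC09_b
MFCC10_a
MFCC10_b
MFCC11_a
MFCC11_b
MFCC12_a
MFCC12_b
MFCC13_a
MFCC13_b
MFCC14_a
MFCC14_b
MFCC15_a
MFCC15_b
MFCC16_a
MFCC16_b
F1_a
F1_b
F1_c
F1_d
F1_e
F1_g
F2_a
F2_b
F2_c
F2_d
F2_e
F2_g
F3_a
F3_b
F3_c
F3_d
F3_e
F3_g
TotalArea
AIUArea
Angle
PauseDist_a
PauseDist_b
PauseDist_c
PauseDist_d
PauseDist_e
PauseDist_g
PauseMax
UttDist_a
UttDist_b
UttDist_e
UttDist_g
PauseCount
Unvoiced_i
SpeechRate
ArticRate
PhonationRatio
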