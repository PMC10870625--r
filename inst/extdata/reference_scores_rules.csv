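class,precision,recall,f1,support
DATE,0.9927,0.9972,0.9950,2178
DOCTOR,0.9535,0.9196,0.9362,1293
VILLE,0.9713,0.9837,0.9775,860
PHONE,0.9967,0.9869,0.9918,612
PATIENT,0.5530,0.8375,0.6661,480
ZIP,0.9968,0.9231,0.9585,338
STR,0.9105,0.6431,0.7538,269
EMAIL,0.9135,1.0000,0.9548,95
micro avg,0.9275,0.9458,0.9365,6125
macro avg,0.9110,0.9114,0.9042,6125
weighted avg,0.9427,0.9458,0.9408,6125
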