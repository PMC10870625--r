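class,precision,recall,f1,support
DATE,0.9922,0.9745,0.9832,2078
DOCTOR,0.9283,0.9229,0.9256,1206
VILLE,0.9987,0.9921,0.9954,764
PHONE,0.9832,0.9670,0.9750,545
PATIENT,0.9726,0.9745,0.9736,510
ZIP,1.0000,0.9727,0.9862,293
STR,0.9520,0.9316,0.9414,234
EMAIL,0.9896,0.9896,0.9896,96
micro avg,0.9756,0.9637,0.9696,5726
macro avg,0.9771,0.9637,0.9713,5726
weighted avg,0.9757,0.9637,0.9696,5726
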