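id,white_pixels,planimetry_cm2,normalized_mean
patient_01,325,1.12,166
patient_02,722,1.44,174
patient_03,242,0.81,168
patient_04,669,1.96,170
patient_05,2251,2.67,175
patient_06,2565,2.82,190
patient_07,1026,1.98,188
patient_08,917,1.45,174
patient_09,1007,1.62,178
patient_10,1315,1.77,172
patient_11,206,0.72,165
patient_12,1771,1.99,186
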