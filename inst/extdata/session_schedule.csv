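scanner,lesion,volume_l,initial_activity_mbq,acquisition_time_s,time_inaccuracy_s
Siemens Biograph TruePoint 64,L1,15.1,87.2,1730,-20
Siemens Biograph TruePoint 64,L2,15.1,70.8,1883,-1
Siemens Biograph TruePoint 64,L3,15.1,55.8,2600,-18
Mediso AnyScan PET/CT,L1,15.0,88.5,1730,-20
Mediso AnyScan PET/CT,L2,15.0,72.6,1883,-10
Mediso AnyScan PET/CT,L3,15.0,57.6,2600,-8
GE Discovery IQ,L1,15.2,88.1,1730,-4
GE Discovery IQ,L2,15.2,71.9,1883,-4
GE Discovery IQ,L3,15.2,57.1,2600,-4
Philips Gemini TF 64,L1,15.0,89.4,1730,-8
Philips Gemini TF 64,L2,15.0,72.5,1883,-10
Philips Gemini TF 64,L3,15.0,58.1,2600,-6
GE Discovery MI,L1,15.0,89.7,1730,-9
GE Discovery MI,L2,15.0,73.3,1883,-7
GE Discovery MI,L3,15.0,59.1,2600,-2
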