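code,scanner,voxel_x_mm,voxel_y_mm,voxel_z_mm,psf_fwhm_mm,postfilter_fwhm_mm,noise_scale
A,Siemens Biograph TruePoint 64,2.67,2.67,2.67,5.5,5.0,0.10
B,Siemens Biograph TruePoint 64,4.0,4.0,3.0,5.5,5.0,0.09
C,Mediso AnyScan PET/CT,3.0,3.0,3.0,5.0,0.0,0.11
D,GE Discovery IQ,2.73,2.73,2.73,5.1,6.4,0.08
E,GE Discovery IQ,3.64,3.64,3.64,5.1,4.4,0.09
F,Philips Gemini TF 64,4.0,4.0,4.0,4.8,0.0,0.12
G,GE Discovery MI,2.73,2.73,2.73,4.2,0.0,0.06
H,GE Discovery MI,2.73,2.73,2.73,4.4,3.2,0.11
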