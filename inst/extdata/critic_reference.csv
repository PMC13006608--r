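region,variability,conflict,information
head_neck,1.176,0.660,0.776
face,1.031,0.729,0.752
chest,1.387,0.669,0.928
limbs_pelvis,1.486,0.734,1.091
abdomen_pelvis,1.475,0.617,0.910
body_surface,0.560,0.745,0.417
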