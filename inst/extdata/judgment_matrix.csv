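balance,spatial_orientation,rhythm,perceptual_judgment,body_coordination,limb_range
1,0.33,0.33,0.333333333333,0.14,1
3,1,0.33,1,0.14,3
3,3,1,1,0.33,3
3,1,1,1,0.20,3
7,7,3,5,1,7
1,0.33,0.33,0.33,0.14,1
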