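class,ambient,blood,fat,heart,kidney,liver,lung,muscle
ambient,19,0,0,0,0,0,0,0
blood,0,35,3,0,0,0,1,0
fat,1,0,23,0,0,0,0,14
heart,2,1,1,26,1,0,7,0
kidney,0,0,5,3,10,0,6,14
liver,0,0,0,6,0,31,1,0
lung,0,0,0,0,0,0,38,0
muscle,0,0,0,0,0,0,0,38
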