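class,type,center_nm,width_nm,amplitude
ambient,baseline,,,0.30
ambient,slope,,,0.00005
ambient,step,600,15,0.03
ambient,gauss,760,12,-0.012
ambient,gauss,495,25,0.05
ambient,gauss,436,9,0.30
ambient,gauss,546,9,0.35
ambient,gauss,611,9,0.25
blood,baseline,,,0.10
blood,slope,,,0.00030
blood,step,600,15,0.30
blood,gauss,760,12,-0.05
blood,gauss,495,25,0.04
blood,gauss,542,12,-0.04
blood,gauss,577,10,-0.04
blood,gauss,920,25,0.12
blood,gauss,975,25,0.10
fat,baseline,,,0.35
fat,slope,,,0.00020
fat,step,600,15,0.18
fat,gauss,760,12,-0.06
fat,gauss,495,25,0.16
fat,gauss,930,20,-0.05
fat,gauss,980,30,-0.02
muscle,baseline,,,0.34
muscle,slope,,,0.00021
muscle,step,600,15,0.20
muscle,gauss,760,12,-0.07
muscle,gauss,495,25,0.14
muscle,gauss,930,20,-0.035
muscle,gauss,980,30,-0.03
heart,baseline,,,0.26
heart,slope,,,0.00018
heart,step,600,15,0.28
heart,gauss,760,12,-0.09
heart,gauss,495,25,0.09
heart,gauss,560,20,-0.07
heart,gauss,980,30,-0.06
kidney,baseline,,,0.32
kidney,slope,,,0.00012
kidney,step,600,15,0.22
kidney,gauss,760,12,-0.10
kidney,gauss,495,25,0.12
kidney,gauss,835,40,0.08
kidney,gauss,980,30,-0.05
liver,baseline,,,0.22
liver,slope,,,0.00010
liver,step,600,15,0.20
liver,gauss,760,12,-0.12
liver,gauss,495,25,0.08
liver,gauss,690,50,-0.06
liver,gauss,980,30,-0.07
lung,baseline,,,0.40
lung,slope,,,0.00025
lung,step,600,15,0.28
lung,gauss,760,12,-0.07
lung,gauss,495,25,0.18
lung,gauss,640,40,0.05
lung,gauss,980,30,-0.03
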