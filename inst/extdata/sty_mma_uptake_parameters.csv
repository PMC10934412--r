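sample_id,cell_line,u_s,u_l,u_p_ref,er
Sty0MMA0.8F,RAW,51,41,60,4
Sty0MMA0.6F,RAW,57,45,69,7
Sty0MMA0.4F,RAW,66,50,82,10
Sty0MMA0.2F,RAW,67,64,71,10
Sty25MMA1.0F,RAW,59,46,71,9
Sty25MMA0.8F,RAW,64,53,75,8
Sty25MMA0.6F,RAW,70,52,89,10
Sty25MMA0.4F,RAW,58,46,71,9
Sty50MMA1.0F,RAW,71,69,72,8
Sty50MMA0.8F,RAW,74,74,75,8
Sty50MMA0.6F,RAW,54,58,50,8
Sty50MMA0.4F,RAW,65,70,59,7
Sty75MMA1.0F,RAW,74,56,92,5
Sty75MMA0.8F,RAW,72,65,79,5
Sty75MMA0.6F,RAW,73,72,73,3
Sty75MMA0.4F,RAW,71,74,69,6
Sty75MMA0.2F,RAW,73,72,74,12
Sty100MMA1.0F,RAW,0.88,0.12,-,-
Sty100MMA0.8F,RAW,65,38,92,3
Sty100MMA0.6F,RAW,69,26,100,8
Sty100MMA0.2F,RAW,67,49,85,9
Sty0MMA0.8F,HEK,24,18,29,11
Sty0MMA0.6F,HEK,43,37,48,10
Sty0MMA0.4F,HEK,40,32,47,7
Sty0MMA0.2F,HEK,27,28,26,10
Sty25MMA1.0F,HEK,35,30,40,11
Sty25MMA0.8F,HEK,58,54,61,8
Sty25MMA0.6F,HEK,45,36,54,8
Sty25MMA0.4F,HEK,43,35,51,10
Sty50MMA1.0F,HEK,67,74,61,8
Sty50MMA0.8F,HEK,68,72,64,7
Sty50MMA0.6F,HEK,24,27,-,16
Sty50MMA0.4F,HEK,15,17,-,12
Sty75MMA1.0F,HEK,73,60,86,7
Sty75MMA0.8F,HEK,74,73,76,8
Sty75MMA0.6F,HEK,74,82,65,8
Sty75MMA0.4F,HEK,71,85,57,7
Sty75MMA0.2F,HEK,33,39,-,7
Sty100MMA1.0F,HEK,13,3.1,-,9
Sty100MMA0.8F,HEK,76,64,89,5
Sty100MMA0.6F,HEK,53,24,81,8
Sty100MMA0.2F,HEK,67,68,65,6
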