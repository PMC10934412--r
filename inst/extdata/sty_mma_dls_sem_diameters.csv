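sample_id,d_sem,d_dls,r_printed,footnote
Sty0MMA0.8N,500,1469,2.9,aggregated
Sty0MMA0.8F,400,1800,4.5,aggregated
Sty0MMA0.2N,300,1509,5.0,aggregated
Sty0MMA0.2F,500,401,0.8,
Sty25MMA1.0N,500,555,1.1,
Sty25MMA1.0F,800,460,0.6,over_approximated
Sty25MMA0.2N,300,358,1.2,
Sty25MMA0.2F,-,238,-,agglomerates_no_single_particles
Sty50MMA1.0N,600,706,1.2,
Sty50MMA1.0F,800,490,0.6,over_approximated
Sty50MMA0.2N,200,189,0.9,
Sty50MMA0.2F,250,259,1.0,
Sty75MMA1.0N,400,398,1.0,
Sty75MMA1.0F,500,407,0.8,
Sty75MMA0.2N,400,409,1.0,
Sty75MMA0.2F,350,237,0.7,over_approximated
Sty100MMA1.0N,600,561,0.9,
Sty100MMA1.0F,700,420,0.6,over_approximated
Sty100MMA0.2N,500,505,1.0,
Sty100MMA0.2F,500,308,0.6,over_approximated
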