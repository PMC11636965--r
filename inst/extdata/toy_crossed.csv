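id,kappa,t1,t2,a1,a2,u,delta,x1_b,x1_c
1,2,0,0.6,0,1,2.4,1,1,0.31
2,1,0,,1,,0.4,1,0,-0.82
3,2,0,0.7,1,0,3.1,0,1,1.05
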