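study,ID,age,gender,education,test,score
1,1,-2.21,-1,3.68,1,0.08
1,1,-2.21,-1,3.68,2,1.59
1,2,22.79,1,-0.32,1,0.72
1,2,22.79,1,-0.32,2,2.06
2,1,-25.21,1,0.68,2,0.19
2,1,-25.21,1,0.68,3,1.26
2,2,-11.21,1,1.68,2,0.04
2,2,-11.21,1,1.68,3,-0.29
2,3,3.79,-1,0.68,2,-0.65
2,3,3.79,-1,0.68,3,-0.51
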