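distance,model1,model2
2.7,0.6,1.4
2.5,2.4,4.6
2.3,6.9,10.2
2.1,12.5,12.0
1.9,3.8,3.7
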