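# modes: E_MB=relative E_LB=relative E_solv_eps4=absolute E_solv_eps80=absolute ZPE=relative
model_id,state,E_MB,E_LB,E_solv_eps4,E_solv_eps80,ZPE
model1,initial,0.0,0.0,-33.3,-45.7,0.0
model1,TS,12.7,15.0,-29.7,-40.7,0.1
model1,final,-18.6,-13.2,-28.2,-38.6,1.7
model2,initial,0.0,0.0,-32.6,-44.6,0.0
model2,TS,13.3,15.1,-29.2,-40.0,-1.0
model2,final,-22.2,-18.2,-27.0,-36.9,1.56
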