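strain,condition,activation_time,steady_state_level,time_to_half,activation_to_half
HTZ1,primary,204.8,0.9,234.3,29.5
htz1_delta,primary,214.1,0.7,362.4,148.3
htz1_K3.8.10.14R,primary,191.3,0.8,375.4,184.2
HTZ1_CRY1,primary,204.4,0.8,243.7,39.3
htz1_delta_DBY50,primary,218.9,0.7,356.3,137.4
HTZ1,secondary,0,0.9,14.8,14.8
htz1_delta,secondary,0,0.6,38.9,38.9
htz1_K3.8.10.14R,secondary,0,0.7,29.7,29.7
HTZ1_CRY1,secondary,0,1.0,28.4,28.4
htz1_delta_DBY50,secondary,0,0.7,110.4,110.4
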