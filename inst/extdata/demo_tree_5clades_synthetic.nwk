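((((Mytilida_1:0.1,Mytilida_2:0.1):0.1,(Mytilida_3:0.1,Mytilida_4:0.1):0.1):0.08,((Ostreida_1:0.1,Ostreida_2:0.1):0.1,(Ostreida_3:0.1,Ostreida_4:0.1):0.1):0.08):0.06,(((Limida_1:0.1,Limida_2:0.1):0.1,(Limida_3:0.1,Limida_4:0.1):0.1):0.08,((Pectinida_1:0.1,Pectinida_2:0.1):0.1,(Pectinida_3:0.1,Pectinida_4:0.1):0.1):0.08):0.06,((Arcida_1:0.1,Arcida_2:0.1):0.1,(Arcida_3:0.1,Arcida_4:0.1):0.1):0.12);
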