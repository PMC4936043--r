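# synthetic clade hypotheses for the packaged demo tree
basal_Arcida	Mytilida_1,Mytilida_2,Mytilida_3,Mytilida_4,Ostreida_1,Ostreida_2,Ostreida_3,Ostreida_4,Limida_1,Limida_2,Limida_3,Limida_4,Pectinida_1,Pectinida_2,Pectinida_3,Pectinida_4
Mytilida_Ostreida	Mytilida_1,Mytilida_2,Mytilida_3,Mytilida_4,Ostreida_1,Ostreida_2,Ostreida_3,Ostreida_4
Limida_Pectinida	Limida_1,Limida_2,Limida_3,Limida_4,Pectinida_1,Pectinida_2,Pectinida_3,Pectinida_4
Mytilida_monophyly	Mytilida_1,Mytilida_2,Mytilida_3,Mytilida_4
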