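name,regions,label
Fatty acid,0.9;1.28,1
Leucine/Isoleucine/Valine,0.98-1.05,2
Lactate,1.33,3
Alanine,1.48,4
Acetate,1.92,5
Glutamine + Glutamate,2.03;2.16;2.34,6
Succinate,2.41,7
Beta-alanine,2.56,8
Dimethylamine,2.75,9
Lysine,3.01,10
Choline,3.22,11
Glucose,3.23-4.0;4.62;5.23,12
Maltose,3.5-4.0;4.45;5.42,13
Glycerol,4.1;4.15,14
Methyl-histidine,7.12,not shown
Histidine,7.94,not shown
Tyrosine,6.89;7.2,not shown
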