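table,drug,cell,note
properties,c,MP,digit grouping ambiguous in source rendering; 65.73 chosen (possibly a collapsed 65-73 melting range)
properties,c,E,digit grouping ambiguous in source rendering; 78.8 chosen
indices,g,avec,reconstructed as 7.7826 (zeta=179 with n=23); source rendering shows 7.7823 with one digit dropped
indices,g,m1_star,digit grouping ambiguous in source rendering; 393 chosen (consistent with avec reconstruction)
indices,g,m1_dstar,digit grouping ambiguous in source rendering; 7135 chosen
indices,g,m2_star,digit grouping ambiguous in source rendering; 1516 chosen
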