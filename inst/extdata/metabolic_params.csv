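group,ln_i0,a,E
Insecta,23.055,0.695,0.686
Arachnida,22.286,0.565,0.660
Myriapoda,22.347,0.568,0.667
Crustacea,23.573,0.698,0.710
Other,23.055,0.695,0.686
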