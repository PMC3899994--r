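((og2:0.186034,og1:0.07541):0.2182,(((g2:0.152019,g3:0.341619):0.099757,g1:0.187731):0.101524,g4:0.119443):0.052611);
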