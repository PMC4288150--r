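ID URS1_synthetic
XX
P0      A      C      G      T
01      1      1      1      7      T
02      7      1      1      1      A
03      1      1      7      1      G
04      1      7      1      1      C
05      1      7      1      1      C
06      1      1      7      1      G
07      1      7      1      1      C
08      1      7      1      1      C
09      1      1      7      1      G
10      7      1      1      1      A
XX
//
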