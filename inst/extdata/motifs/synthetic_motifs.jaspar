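>AP1 synthetic AP-1 (bZIP TGACTCA core, sharpened 13-bp)
A [   1   1   1 147   1   1   1 147   1   1 147   1   1 ]
C [   1   1   1   1 147   1 147   1   1 147   1   1 147 ]
G [ 147   1 147   1   1   1   1   1   1   1   1 147   1 ]
T [   1 147   1   1   1 147   1   1 147   1   1   1   1 ]
>TEAD synthetic TEAD monomer (MCAT GGAATG core, sharpened 13-bp)
A [ 147   1   1   1 147 147   1   1   1   1   1 147   1 ]
C [   1 147   1   1   1   1   1   1   1 147   1   1 147 ]
G [   1   1 147 147   1   1   1 147   1   1 147   1   1 ]
T [   1   1   1   1   1   1 147   1 147   1   1   1   1 ]
>TEAD_DIMER synthetic TEAD dimer (two GGAATG half-sites, 13-bp)
A [   1   1 147 147   1   1   1   1   1 147 147   1   1 ]
C [   1   1   1   1   1   1   1   1   1   1   1   1   1 ]
G [ 147 147   1   1   1 147   1 147 147   1   1   1 147 ]
T [   1   1   1   1 147   1 147   1   1   1   1 147   1 ]
>STAT3 synthetic STAT3 (TTCCNGGAA-like core, sharpened 13-bp)
A [   1   1   1   1   1   1   1   1 147 147   1   1   1 ]
C [ 147   1   1 147 147 147   1   1   1   1   1   1   1 ]
G [   1   1   1   1   1   1 147 147   1   1 147   1 147 ]
T [   1 147 147   1   1   1   1   1   1   1   1 147   1 ]
>CEBP synthetic CEBP (TTGCGCAA core, sharpened 13-bp)
A [   1 147   1   1   1   1   1   1 147 147   1   1   1 ]
C [   1   1   1   1   1 147   1 147   1   1   1 147   1 ]
G [ 147   1   1   1 147   1 147   1   1   1   1   1 147 ]
T [   1   1 147 147   1   1   1   1   1   1 147   1   1 ]
>NFKB synthetic NF-kB (GGGACTTTCC core, sharpened 13-bp)
A [ 147   1   1   1 147   1   1   1   1   1   1 147   1 ]
C [   1   1   1   1   1 147   1   1   1 147 147   1   1 ]
G [   1 147 147 147   1   1   1   1   1   1   1   1 147 ]
T [   1   1   1   1   1   1 147 147 147   1   1   1   1 ]
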