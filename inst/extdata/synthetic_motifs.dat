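AC  V$SYNA_01
XX
ID  V$SYNA_01
XX
P0      A      C      G      T
01     85      5      5      5     A
02      5     85      5      5     C
03      5      5     85      5     G
04      5      5      5     85     T
05     85      5      5      5     A
06      5     85      5      5     C
07     40     40     10     10     M
08      5      5     85      5     G
09      5      5      5     85     T
10     85      5      5      5     A
XX
//
AC  V$SYNB_01
XX
ID  V$SYNB_01
XX
P0      A      C      G      T
01      5      5      5     85     T
02      5      5     85      5     G
03     85      5      5      5     A
04      5      5      5     85     T
05      5     85      5      5     C
06     85      5      5      5     A
07      5      5     85      5     G
08     25     25     25     25     N
09      5     85      5      5     C
10      5      5      5     85     T
XX
//
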