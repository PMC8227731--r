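>SYN0001.1 SYNA
A [ 85  5  5  5 85  5 40  5  5 85 ]
C [  5 85  5  5  5 85 40  5 85  5 ]
G [  5  5 85  5  5  5 10 85  5  5 ]
T [  5  5  5 85  5  5 10  5  5  5 ]
>SYN0002.1 SYNB
A [  5  5 85  5  5 85  5 25  5  5 ]
C [  5  5  5  5 85  5  5 25 85  5 ]
G [  5 85  5  5  5  5 85 25  5  5 ]
T [ 85  5  5 85  5  5  5 25  5 85 ]
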