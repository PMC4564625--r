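offset,n
L+5,2
L+4,2
L+3,3
L+2,8
L+1,12
L,29
L-1,29
L-2,24
L-3,16
L-4,13
L-5,12
L-6,8
L-7,6
L-8,5
L-9,4
L-10,3
L-11,2
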