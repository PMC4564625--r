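offset,n
L+5,0
L+4,0
L+3,1
L+2,3
L+1,1
L,13
L-1,9
L-2,6
L-3,3
L-4,2
L-5,2
L-6,2
L-7,1
L-8,0
L-9,1
L-10,0
L-11,1
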