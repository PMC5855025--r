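subject,r1,r2,r3,r4,r5,r6,r7,r8,r9,r10,r11,r12,r13,r14,r15,r16,r17,r18
S01,6,13,15,17,14,18,16,9,5,1,12,7,8,3,11,4,2,10
S02,16,15,6,17,14,9,18,13,1,5,12,7,11,8,3,2,4,10
S03,16,15,6,14,17,18,9,13,12,5,1,7,8,11,3,2,4,10
S04,15,13,16,14,6,18,9,17,1,5,7,12,11,8,3,2,4,10
S05,1,15,6,17,16,14,18,9,13,5,12,7,11,8,3,2,10,4
S06,15,13,17,6,14,18,9,16,5,1,12,2,4,8,3,11,7,10
S07,6,15,14,16,9,18,17,13,12,11,7,5,1,4,2,3,8,10
S08,6,15,13,14,9,16,18,17,12,5,1,7,11,8,3,4,2,10
S09,6,17,1,15,14,18,13,16,9,5,12,7,11,8,3,2,10,4
S10,15,6,14,17,18,13,9,16,5,12,1,11,7,2,4,3,8,10
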