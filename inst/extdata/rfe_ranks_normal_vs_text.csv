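subject,r1,r2,r3,r4,r5,r6,r7,r8,r9,r10,r11,r12,r13,r14,r15,r16,r17,r18
S01,15,6,17,14,18,9,16,13,5,1,12,7,11,3,8,2,10,4
S02,15,6,17,14,18,16,9,13,12,7,11,5,1,3,8,10,2,4
S03,5,6,15,17,18,14,16,9,13,1,12,7,11,3,4,2,8,10
S04,17,15,13,18,14,6,16,9,1,12,5,7,11,3,8,2,10,4
S05,6,17,15,16,14,18,9,13,5,1,12,7,11,3,8,2,4,10
S06,17,16,6,15,18,14,9,13,1,2,4,12,5,8,3,11,7,10
S07,15,17,9,14,18,16,13,12,8,11,10,7,6,5,4,3,2,1
S08,5,15,6,17,14,18,16,9,13,12,7,8,11,10,4,3,2,1
S09,5,6,17,15,18,14,9,16,13,1,12,7,11,8,3,2,4,10
S10,15,17,12,14,18,13,9,6,16,11,5,1,8,3,2,4,7,10
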