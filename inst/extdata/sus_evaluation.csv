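SUS_1,SUS_2,SUS_3,SUS_4,SUS_5,SUS_6,SUS_7,SUS_8,SUS_9,SUS_10
4,2,4,1,5,1,5,1,4,2
3,1,5,1,4,1,4,1,3,2
4,1,5,1,5,1,5,1,5,1
5,3,4,2,4,1,4,2,4,1
3,3,4,2,3,2,4,2,3,2
2,1,5,1,4,2,5,2,3,1
4,2,5,2,4,1,5,1,5,1
2,3,3,3,2,4,3,4,4,4
2,3,4,2,3,3,2,3,1,3
4,1,4,3,5,1,4,2,3,1
3,2,5,2,4,2,4,1,3,2
2,2,4,1,2,2,3,2,4,1
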