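cell_id,gene001,gene002,gene003,gene004,gene005,gene006,gene007,gene008
cell0001,3,1,3,1,3,0,0,10
cell0002,1,2,6,1,4,1,0,2
cell0003,5,6,1,3,0,2,6,0
cell0004,1,4,0,0,2,5,2,8
cell0005,3,1,2,0,3,2,8,0
cell0006,4,2,2,2,1,1,0,0
cell0007,7,3,4,1,2,2,1,0
cell0008,5,7,0,0,8,0,5,0
cell0009,0,0,1,0,4,2,0,45
cell0010,4,3,0,2,4,3,6,1
cell0011,2,0,1,0,0,1,4,11
cell0012,0,0,2,0,7,3,4,5
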