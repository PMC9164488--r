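cell_id,cell_type
cell0001,T2
cell0002,T2
cell0003,T1
cell0004,T1
cell0005,T2
cell0006,T1
cell0007,T1
cell0008,T1
cell0009,T2
cell0010,T1
cell0011,T2
cell0012,T2
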