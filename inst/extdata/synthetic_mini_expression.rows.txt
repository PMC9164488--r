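cell0001
cell0002
cell0003
cell0004
cell0005
cell0006
cell0007
cell0008
cell0009
cell0010
cell0011
cell0012
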