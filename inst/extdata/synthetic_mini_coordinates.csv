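cell_id,x,y
cell0001,1.76618664828129,0.700317789241672
cell0002,1.21792912371457,1.71267615347169
cell0003,0.77864150959067,3.96467661079951
cell0004,3.87725607533939,2.87417383580469
cell0005,0.728361735958606,0.805720841186121
cell0006,0.767195505043492,3.28402766869403
cell0007,2.10826150625944,3.10509763187729
cell0008,4.20999909006059,4.10857285051607
cell0009,3.17840947383083,1.73247510353103
cell0010,2.87538430108689,4.27967193182558
cell0011,3.06914830505848,0.713282709335908
cell0012,4.18934995378368,2.08842049329542
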