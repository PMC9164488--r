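gene001
gene002
gene003
gene004
gene005
gene006
gene007
gene008
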