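predicted,normal,mild,moderate,severe
normal,3,0,0,0
mild,0,8,3,0
moderate,0,0,11,3
severe,0,0,0,28
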