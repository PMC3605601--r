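donor_id,has_disease,age
d1,1,61
d2,0,45
d3,1,52
d4,0,70
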