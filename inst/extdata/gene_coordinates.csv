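"gene","coordinate_bp","genome_length_bp"
"ctrA",3240000,4016942
"pleC",2531000,4016942
"perP",1900000,4016942
"podJ",3080000,4016942
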