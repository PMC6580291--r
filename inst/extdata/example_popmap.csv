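"pop","species"
1,"arcania"
2,"gardetta"
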