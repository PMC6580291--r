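arcania_01	1	1	1	1	2	-9	2	2	1	1	1	2	1	2	1	1	1	1	2	1	2
arcania_01	1	1	1	1	1	-9	1	1	1	1	1	2	1	1	1	1	1	1	1	1	1
arcania_02	1	1	1	1	1	1	2	2	1	1	1	2	2	2	1	1	1	2	-9	2	2
arcania_02	1	1	1	1	1	1	1	1	1	1	1	2	1	1	1	1	1	2	-9	2	1
arcania_03	1	2	1	1	1	1	1	1	1	1	2	2	2	2	1	2	1	1	1	2	2
arcania_03	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	2	2
gardetta_01	2	1	1	2	1	-9	-9	1	2	2	1	-9	1	2	1	1	2	1	2	2	2
gardetta_01	2	1	1	2	1	-9	-9	1	1	1	1	-9	1	2	1	1	1	1	1	2	2
gardetta_02	2	1	1	2	1	2	1	1	1	1	1	2	1	2	1	1	1	1	-9	2	2
gardetta_02	2	1	1	2	1	2	1	1	1	1	1	2	1	1	1	1	1	1	-9	2	2
gardetta_03	2	1	2	2	1	2	1	1	1	1	1	2	1	2	2	1	2	1	2	2	2
gardetta_03	2	1	1	2	1	2	1	1	1	1	1	2	1	1	1	1	1	1	1	2	2
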