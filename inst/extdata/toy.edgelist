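# two triangle modules joined by two bridges (v1-v4, v3-v6)
v1 v2
v1 v3
v2 v3
v1 v4
v4 v5
v4 v6
v5 v6
v3 v6
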