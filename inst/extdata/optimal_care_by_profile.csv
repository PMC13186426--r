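profile,not_optimal,optimal
1,158,794
2,88,351
3,84,410
4,59,281
5,38,149
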