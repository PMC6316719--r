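loop_len	dg
3	5.4
4	5.6
5	5.7
6	5.4
7	6.0
8	5.5
9	6.4
10	6.5
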