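dili_class,side,n
Most,ge,120
Most,lt,55
Less,ge,156
Less,lt,101
No,ge,64
No,lt,156
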