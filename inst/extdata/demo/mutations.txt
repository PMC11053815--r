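# synthetic demo mutation list (generated, not biological)
G14I
S43G
W44A
E58K
D61L
I118Y
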