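{"reference":"black","intercepts":{"blond":0.8,"brown":1,"red":-1.5}}
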