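# Degenerate case: no stimulus; the membrane holds its resting state.
amplitude: 0
duration: 0
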