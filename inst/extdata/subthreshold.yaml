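# Canonical subthreshold run: ~5 mV depolarisation, no spike.
# units: amplitude uA/cm2, times ms
amplitude: 2.5
duration: 3
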