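# Canonical spiking run: one full action potential.
# units: amplitude uA/cm2, times ms
amplitude: 3
duration: 5
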