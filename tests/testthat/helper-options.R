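# Keep filter drop-count logging quiet during tests; warnings still surface.
options(pqtlx.verbose = 0)
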