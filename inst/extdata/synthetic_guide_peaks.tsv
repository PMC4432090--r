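id	direct_ppm	indirect_hz	linewidth_hz
signal1	NA	-200	NA
signal2	NA	-134	NA
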