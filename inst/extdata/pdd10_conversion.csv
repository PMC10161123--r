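# Published specifier conversion pairs: %dd(10) measured at a machine's
# equivalent square field size (ESFS side, cm, at 100 cm) -> %dd(10,10)X.
# Rows: manufacturer conversion at ESFS 6.75 and the code-of-practice
# conversion at ESFS 6.25 for the same measured 64.90% value.
esfs_side,pdd10_esfs,pdd10_10
6.75,64.90,66.94
6.25,64.90,67.42
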