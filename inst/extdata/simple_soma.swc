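# synthetic one-point soma stub (not a reconstructed morphology)
# columns: id type x y z radius parent
1 1 0.0 0.0 0.0 5.0 -1
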