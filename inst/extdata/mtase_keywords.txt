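# Keywords (case-insensitive substrings) matched against annotation terms to
# flag putative SAM-dependent methyltransferases. One per line.
methyltransferase
SAM
S-adenosyl
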