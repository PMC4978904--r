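# Example Cas profile for `pamscape.R design`.  The scaffold below is a
# SYNTHETIC placeholder sequence for demonstration and testing only — it is
# NOT a real tracrRNA-fused scaffold.  Replace `scaffold` with the DNA
# template of the scaffold for your Cas system before designing real oligos.
name = SaCas9
pam_class = NNGRRT
spacer_length = 20
scaffold = GTTTTAGTACTCTGGAAACAGAATCTACTAAAACAAGGCAAAATGCCGTGTTTATCTCGTCAACTTGTTGGCGAGATTTTT
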