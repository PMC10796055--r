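# Study-condition domains used throughout the suite
gauss_heights <- heights_domain("gaussian")
unif_heights <- heights_domain("uniform")
line7 <- syllables_domain("line7")
hex7 <- syllables_domain("hex7")

# turning-point proportion of a sequence after repeat stripping
stripped_tp <- function(s) turning_points(strip_repeats(s))
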