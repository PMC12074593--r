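# shared constants (file sorts before every user of these at load time)

# one-letter codes of the 20 standard amino acids
STANDARD_AA <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

AA_ALPHABET <- c(STANDARD_AA, "X")
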