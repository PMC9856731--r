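# Large sparse systems (n > ~46k unknowns) need 64-bit armadillo indices
PKG_CPPFLAGS = -DARMA_64BIT_WORD=1
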