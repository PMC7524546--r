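# Keep multiply+add separately rounded so the C++ engine reproduces the
# R reference engine's arithmetic bit-for-bit.
PKG_CXXFLAGS = -ffp-contract=off
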