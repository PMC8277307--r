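utils::globalVariables(c("x0", "y0", "x1", "y1", "x", "y", "id",
                         "cx", "cy", "zero", "score"))
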