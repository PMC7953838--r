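## package-wide constants and tiny string helpers (loaded first)

DNA_BASES <- c("A", "C", "G", "T")

## Split one string into single characters (fast path used by the simulator).
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
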