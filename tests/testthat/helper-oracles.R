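# Independent closed-form oracle for delta <-> atom-fraction conversions,
# written directly from the ratio definitions (kept separate from the
# package implementation on purpose).
oracle_fraction <- function(delta, r = 0.011180) {
  ratio <- (delta / 1000 + 1) * r
  ratio / (1 + ratio)
}
oracle_delta <- function(f, r = 0.011180) {
  1000 * (f / (1 - f) / r - 1)
}

# Shared fixture paths
extdata <- function(f) system.file("extdata", f, package = "lipidsip")
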