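# Small internal utilities.

# Derive a stream-specific 31-bit seed from (seed, key) so that pipeline
# stages get independent, reproducible streams and inserting a stage does not
# shift the streams of the others.
derive_seed <- function(seed, key) {
  x <- (as.numeric(seed) %% 2147483647) + 1
  for (k in utf8ToInt(as.character(key))) {
    x <- (x * 31 + k) %% 2147483647
  }
  as.integer(x)
}
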