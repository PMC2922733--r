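# One global integer seed fans out to per-generator streams. Offsets are
# spread by a multiplier larger than the largest offset so that streams for
# different (seed, purpose) pairs never coincide — naive `seed + offset`
# schemes make, say, one replicate's ozone innovations reuse the next
# replicate's weather stream when replicates are seeded consecutively.
seed_stream <- function(seed, offset) {
  base <- (as.integer(seed) %% 1000000L) * 1201L
  set.seed(base + as.integer(offset))
}
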