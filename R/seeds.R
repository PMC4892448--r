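# Deterministic sub-stream seeds. Every top-level generator takes one seed;
# internal stages and per-simulation streams derive their own seeds from it
# so that reordering one stage never perturbs another. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + 104729 * as.double(k) + 1) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  expr
}
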