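## Shared internals: permutation p-values and seed handling.

## Add-one permutation p-value: p = (1 + #{perm >= obs}) / (1 + n_perm).
## Used by every permutation test in the package so that p always lies in
## [1/(n_perm+1), 1].
perm_pvalue <- function(obs, perm) {
  (1 + sum(perm >= obs)) / (1 + length(perm))
}

## Deterministic child seeds: one global seed expanded per stage/replicate so
## stages can be rerun in isolation. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
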