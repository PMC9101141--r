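# pooled draws accessor used by tests (mirrors the package-internal pooling)
pool_draws_test <- function(post, what) {
  parts <- lapply(post$chains, `[[`, what)
  do.call(rbind, parts)
}
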