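# Small synthetic dataset shared by core/evaluation tests: 20 miRNAs x 10
# diseases keeps every leave-one-out style loop fast while preserving the
# planted block structure.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_generate(synthetic_spec(n_mirna = 20L,
                                                  n_disease = 10L,
                                                  rng_seed = 7L))
    cache
  }
})

small_fused <- function(fx = small_fixture()) {
  fuse_mirna_similarity(fx$sm, fx$family)
}

# hand-sized dataset with exact values for deterministic unit checks
tiny_dataset <- function(seed = 42L) {
  set.seed(seed)
  sm <- rand_sim(6L, sprintf("m%d", 1:6))
  sd <- rand_sim(4L, sprintf("d%d", 1:4))
  a <- matrix(0L, 6L, 4L, dimnames = list(rownames(sm), rownames(sd)))
  a[cbind(c(1L, 3L, 2L, 5L, 6L), c(1L, 1L, 2L, 3L, 4L))] <- 1L
  list(sm = sm, sd = sd, a = a)
}
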