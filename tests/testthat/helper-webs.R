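# Small fixture builders shared across the tests.

# 2 species: consumer sp1 is a specialist on producer sp2.
web_specialist <- function() {
  food_web(rbind(c(0, 1), c(0, 0)), species = c("sp1", "sp2"))
}

# 3 species, 2 links: generalist consumer sp1 eats producers sp2, sp3.
web_generalist3 <- function() {
  food_web(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)),
           species = c("sp1", "sp2", "sp3"))
}

# random binary web with an exact link count
random_web <- function(S, L, seed = 1) {
  set.seed(seed)
  A <- matrix(0L, S, S)
  A[sample.int(S * S, L)] <- 1L
  food_web(A, species = paste0("sp", seq_len(S)))
}

# random valid parameter set
random_params <- function(S, seed = 1) {
  set.seed(seed)
  param_set(runif(S), runif(S), runif(S, 0.05, 1))
}

clamp_unit <- function(x) pmin(pmax(x, 0), 1)

quick_cfg <- function(seed = 1, stages = 60, restarts = 2, ...) {
  anneal_config(stages = stages, restarts = restarts, seed = seed, ...)
}
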