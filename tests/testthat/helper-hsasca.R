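sphere <- function(x) sum(x^2)

sphere_space <- function(l = 2, r = 5) search_space(rep(-r, l), rep(r, l))

# Small monitoring dataset + cheap tuning problem for unit tests: few rows
# and few boosting rounds keep a single fitness evaluation ~10 ms.
tiny_problem <- function(seed = 11, n = 80, nrounds = 8) {
  d <- generate_dataset(generator_params(n = n), seed = seed)
  split_dataset(d, seed = seed, nrounds = nrounds)
}

mid_position <- c(0.3, 5, 0.9, 0.9, 6, 0.1)
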