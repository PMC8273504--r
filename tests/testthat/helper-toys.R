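# toy generators shared across the test files

# random haplotype pair over a random sparse site list
random_hap_pair <- function(L, max_sites = 40) {
  k <- sample.int(max_sites, 1)
  pos <- sort(sample.int(L, k) - 1L)
  list(
    hap_a = sample(0:1, k, replace = TRUE),
    hap_b = sample(0:1, k, replace = TRUE),
    site_positions = pos
  )
}

# a small valid sexed population with explicitly chosen haplotypes
toy_population <- function(hap_rows, site_positions, sexes, L,
                           sd_position = NA) {
  new_population(
    haplotypes = do.call(rbind, hap_rows),
    site_positions = site_positions,
    sexes = sexes, sd_position = sd_position, L = L
  )
}

# parameters scaled for fast engine tests
fast_params <- function(...) {
  defaults <- list(N = 20, L = 2000, mu = 1e-4, r = 1e-6, E = 30, W = 200,
                   generations = 200, record_interval = 100, seed = 1)
  args <- modifyList(defaults, list(...))
  do.call(sim_params, args)
}
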