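test_that("window heterozygosity counts: trivial and single-site cases", {
  # no heterozygous sites -> all zero
  expect_equal(het_window_counts(c(0L, 1L), c(0L, 1L), c(10L, 20L),
                                 W = 100, L = 500),
               integer(500))
  # single heterozygous site at p, W = 1000: count 1 exactly for targets
  # in [p - 499, p + 500] (interior case)
  p <- 3000L
  h <- het_window_counts(1L, 0L, p, W = 1000, L = 10000)
  on <- which(h == 1L) - 1L
  expect_equal(range(on), c(p - 499L, p + 500L))
  expect_equal(sum(h), 1000L)
  # two heterozygous sites 100 bp apart share most windows
  h2 <- het_window_counts(c(1L, 1L), c(0L, 0L), c(3000L, 3100L),
                          W = 1000, L = 10000)
  expect_setequal(unique(h2), c(0L, 1L, 2L))
  expect_equal(sum(h2 == 2L), 900L)   # windows containing both sites
})

test_that("sliding-window counts equal the naive window-membership oracle
           on random toy instances", {
  set.seed(101)
  for (rep in 1:300) {
    L <- sample(100:2000, 1)
    W <- sample(2:min(200, L), 1)     # both window parities exercised
    tp <- random_hap_pair(L)
    fast <- het_window_counts(tp$hap_a, tp$hap_b, tp$site_positions, W, L)
    slow <- brute_force_window_counts(tp$hap_a, tp$hap_b,
                                      tp$site_positions, W, L)
    expect_identical(fast, slow)
  }
})

test_that("segment decomposition used by the engine matches the dense
           R computation exactly", {
  set.seed(202)
  for (rep in 1:200) {
    L <- sample(200:2000, 1)
    W <- sample(2:200, 1)
    E <- sample(c(0, 5, 30, 200), 1)
    k <- sample(1:30, 1)
    het <- sort(sample.int(L, k) - 1L)
    seg <- cpp_window_segments(het, E, W, L)
    dense_h <- window_count_profile(het, W, L)
    # expand segments to a dense factor vector
    fac <- numeric(L)
    for (s in seq_along(seg$h)) {
      fac[(seg$bounds[s] + 1):seg$bounds[s + 1]] <- seg$factor[s]
    }
    expect_equal(fac, pmax(0, 1 - E * dense_h / W))
  }
})

test_that("suppression formula: 3% per site, clamping, and E = 0
           neutrality", {
  r0 <- rep(1e-7, 5)
  expect_equal(modified_recomb_probs(r0, rep(1, 5), E = 30, W = 1000),
               0.97 * r0)
  expect_equal(modified_recomb_probs(r0, rep(0, 5), E = 30, W = 1000), r0)
  # 30 * 34 / 1000 = 1.02 > 1: clamped to zero
  expect_equal(modified_recomb_probs(r0, rep(34, 5), E = 30, W = 1000),
               numeric(5))
})

test_that("E = 0 leaves every baseline probability untouched", {
  set.seed(7)
  for (rep in 1:20) {
    r0 <- runif(200, 0, 1e-5)
    h <- sample(0:500, 200, replace = TRUE)
    expect_identical(modified_recomb_probs(r0, h, E = 0, W = 1000), r0)
  }
})

test_that("adding a heterozygous site never increases any r_i, and r_i
           stays within [0, r0]", {
  set.seed(33)
  L <- 1500; W <- 120; E <- 25
  r0 <- runif(L, 0, 1e-5)
  for (rep in 1:50) {
    k <- sample(1:20, 1)
    het <- sort(sample.int(L, k + 1) - 1L)
    ri_small <- modified_recomb_probs(
      r0, window_count_profile(het[-1], W, L), E, W)
    ri_big <- modified_recomb_probs(
      r0, window_count_profile(het, W, L), E, W)
    expect_true(all(ri_big <= ri_small + 1e-18))
    expect_true(all(ri_big >= 0 & ri_big <= r0))
  }
})

test_that("the SD site suppresses its own neighbourhood in every male
           meiosis from generation 0", {
  p <- sim_params(N = 10, L = 2000, E = 30, W = 200)
  pop <- init_population(p, 1)
  ls <- make_landscape(p)
  male1 <- which(pop$sexes == "male")[1]
  ctx <- meiosis_context(pop$haplotypes[2 * male1 - 1, ],
                         pop$haplotypes[2 * male1, ],
                         pop$site_positions, "male", ls, p$E, p$W)
  near <- abs(seq.int(0, p$L - 1) - p$sd_position) < p$W / 2
  expect_true(all(ctx$h_counts[near] >= 1))
  expect_true(all(ctx$r_i[near] <= (1 - p$E / p$W) * ctx$r0[near] + 1e-20))
})

test_that("crossover sampling is per-position Bernoulli with the given
           probabilities", {
  expect_equal(sample_crossovers(numeric(100)), integer(0))
  set.seed(55)
  ri <- c(0.5, 0.1, 0, 0.25, 0.9, 0.01, 0.3, 0, 0.66, 0.05)
  ndraw <- 1e5
  hits <- numeric(10)
  u <- matrix(runif(10 * ndraw), nrow = ndraw)
  hits <- colSums(sweep(u, 2, ri, `<`))
  se <- sqrt(ri * (1 - ri) * ndraw)
  expect_true(all(abs(hits - ndraw * ri) <= 3 * se + 1e-9))
  # and the function itself agrees with that field on a smaller sample
  cnt <- numeric(10)
  for (i in 1:20000) {
    bp <- sample_crossovers(ri)
    cnt[bp + 1] <- cnt[bp + 1] + 1
  }
  se2 <- sqrt(ri * (1 - ri) * 20000)
  expect_true(all(abs(cnt - 20000 * ri) <= 4 * se2 + 1e-9))
})

test_that("gamete formation: copies a parent without breakpoints, switches
           at breakpoints, and transmits Y to half the male gametes", {
  p <- sim_params(N = 10, L = 1000, E = 30, W = 100)
  ls <- make_landscape(p)
  # male haplotype pair: hap_a carries Y at the SD (position 500)
  ctx <- meiosis_context(hap_a = c(1L, 1L), hap_b = c(0L, 0L),
                         site_positions = c(200L, 500L), sex = "male",
                         landscape = ls, E = p$E, W = p$W)
  g_a <- form_gamete(ctx, integer(0), sd_position = 500L, start = "a")
  expect_equal(g_a$haplotype, c(1L, 1L))
  expect_equal(g_a$sd_allele, "Y")
  # one breakpoint left of the SD, starting on the X haplotype -> Y at SD
  g_sw <- form_gamete(ctx, breakpoints = 300L, sd_position = 500L,
                      start = "b")
  expect_equal(g_sw$haplotype, c(0L, 1L))
  expect_equal(g_sw$sd_allele, "Y")
  # breakpoint exactly at a site position switches that site too
  g_at <- form_gamete(ctx, breakpoints = 500L, sd_position = 500L,
                      start = "b")
  expect_equal(g_at$haplotype, c(0L, 1L))
  set.seed(77)
  y <- replicate(10000, form_gamete(ctx, integer(0),
                                    sd_position = 500L)$sd_allele)
  frac <- mean(y == "Y")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})
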