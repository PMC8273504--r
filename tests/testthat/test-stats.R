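test_that("NRR is zero at generation 0: a single heterozygous SD cannot
           silence its window", {
  p <- sim_params(N = 10, L = 2000, E = 30, W = 1000)
  pop <- init_population(p, 1)
  expect_equal(nrr_size(pop, make_landscape(p), p), 0L)
})

test_that("NRR spans the saturated window region on a constructed toy
           genome", {
  # every individual heterozygous at the same ceil(W/E) = 5 clustered sites:
  # windows holding all 5 sites are fully suppressed for everyone
  L <- 400L; W <- 100L; E <- 20
  p <- sim_params(N = 4, L = L, E = E, W = W)
  sd <- p$sd_position                       # 200
  sites <- sort(c(sd, sd + c(-20L, -10L, 10L, 20L)))
  hapA <- rep(1L, 5); hapB <- rep(0L, 5)
  rows <- rep(list(hapA, hapB), 4)
  pop <- toy_population(rows, sites, c("male", "male", "female", "female"),
                        L, sd_position = sd)
  ls <- make_landscape(p)
  got <- nrr_size(pop, ls, p)
  # brute-force expectation from the definition: the ok-run containing sd
  h <- brute_force_window_counts(hapA, hapB, sites, W, L)
  ok <- (1 - E * h / W) <= 0
  expect_true(ok[sd + 1])
  lo <- sd + 1; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- sd + 1; while (hi < L && ok[hi + 1]) hi <- hi + 1
  expect_gt(got, 0)
  expect_equal(got, hi - lo + 1L)
})

test_that("a zero-baseline landscape makes the whole sequence
           non-recombining", {
  p <- sim_params(N = 6, L = 500, r = 0, E = 30, W = 100)
  pop <- init_population(p, 2)
  expect_equal(nrr_size(pop, make_landscape(p), p), p$L)
})

test_that("the males-only NRR is never smaller than the all-individuals
           NRR", {
  for (s in 1:5) {
    p <- sim_params(N = 16, L = 2000, mu = 1e-4, r = 1e-6, E = 30, W = 200,
                    generations = 300, record_interval = 300, seed = s)
    pop <- run(p, record_profiles = "none")$final_population
    ls <- make_landscape(p)
    p_m <- p; p_m$nrr_scope <- "males_only"
    p_a <- p; p_a$nrr_scope <- "all_individuals"
    expect_gte(nrr_size(pop, ls, p_m), nrr_size(pop, ls, p_a))
  }
})

test_that("divergence means: SD-only population and a hand-counted toy", {
  p <- sim_params(N = 10, L = 1000)
  pop <- init_population(p, 3)
  d <- divergence_means(pop)
  expect_equal(unname(d), c(0, 1 / p$L))      # dxx = 0, dxy = 1/L
  # 3 males, each heterozygous at 2 of 10 sites, L = 10 -> dxy = 0.2
  sites <- 0:9
  m_a <- c(1L,1L,0L,0L,0L,0L,0L,0L,0L,0L); m_b <- integer(10)
  rows <- list(m_a, m_b, m_a, m_b, m_a, m_b,
               integer(10), integer(10))     # plus one female, identical
  pop2 <- toy_population(rows, sites,
                         c("male", "male", "male", "female"), L = 10L,
                         sd_position = 0L)
  d2 <- divergence_means(pop2)
  expect_equal(unname(d2["dxy"]), 0.2)
  expect_equal(unname(d2["dxx"]), 0)
})

test_that("Hudson male-female FST: closed-form cases", {
  p <- sim_params(N = 10, L = 100, W = 50)
  pop <- init_population(p, 4)
  fst <- fst_profile(pop)
  # SD position: p_m = 1/2, p_f = 0 -> 0.5
  expect_equal(fst[pop$sd_position + 1], 0.5)
  # all non-segregating positions are defined as 0
  expect_equal(fst[-(pop$sd_position + 1)], numeric(p$L - 1))
  # equal frequencies in both sexes -> 0
  rows <- list(c(1L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 0L))
  pop2 <- toy_population(rows, c(2L, 5L), c("male", "female"), L = 10L,
                         sd_position = 2L)
  expect_equal(fst_profile(pop2), numeric(10))
})

test_that("FST profile matches a naive per-site two-pool computation on
           random toy populations", {
  set.seed(41)
  for (rep in 1:30) {
    N <- 8; L <- 60L
    k <- sample(3:12, 1)
    sites <- sort(sample.int(L, k) - 1L)
    rows <- lapply(1:(2 * N), function(i) sample(0:1, k, replace = TRUE))
    sexes <- sample(rep(c("male", "female"), N / 2))
    pop <- toy_population(rows, sites, sexes, L, sd_position = NA)
    got <- fst_profile(pop)
    hap_sex <- rep(sexes, each = 2)
    for (j in seq_len(k)) {
      col <- vapply(rows, `[`, 0L, j)
      pm <- mean(col[hap_sex == "male"])
      pf <- mean(col[hap_sex == "female"])
      hb <- pm * (1 - pf) + pf * (1 - pm)
      hw <- (2 * pm * (1 - pm) + 2 * pf * (1 - pf)) / 2
      want <- if (hb > 0) (hb - hw) / hb else 0
      expect_equal(got[sites[j] + 1], want)
    }
  }
})

test_that("pairwise diversity by pool matches a hand computation", {
  # 2 individuals (1 male, 1 female), 2 sites, L = 10
  rows <- list(c(1L, 1L), c(0L, 0L),     # male: Y = carries SD at site 0
               c(0L, 1L), c(0L, 0L))     # female
  pop <- toy_population(rows, c(0L, 4L), c("male", "female"), L = 10L,
                        sd_position = 0L)
  # all pool: site0 count 1 -> 1*3; site4 count 2 -> 2*2; pairs = 6
  expect_equal(pairwise_diversity(pop, "all"), (3 + 4) / 6 / 10)
  # X pool (3 haplotypes): site4 count 2 of 3 -> 2*1; pairs = 3
  expect_equal(pairwise_diversity(pop, "X"), 2 / 3 / 10)
  expect_error(pairwise_diversity(pop, "Y"), "fewer than two")
})

test_that("summarize_replicates aggregates a raw time-series table", {
  df <- data.frame(replicate = rep(1:2, each = 2),
                   generation = rep(c(0, 100), 2),
                   nrr_bp = c(0, 10, 0, 30))
  sm <- summarize_replicates(df)
  expect_equal(sm$nrr_bp_mean, c(0, 20))
  expect_equal(sm$nrr_bp_sd, c(0, sd(c(10, 30))))
})
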