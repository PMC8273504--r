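# Brute-force reference implementations for the test surface.  These
# re-derive everything from the definitions by literal scans and never call
# the sliding-window or compiled fast paths they are used to check.

#' Naive window heterozygosity counts (reference implementation)
#'
#' For each target position `i` in `[0, L)`, literally counts the
#' heterozygous sites inside the window `[i - floor(W/2), i + W - floor(W/2))`
#' by direct membership scan.  O(L*k); intended for toy sizes (L <= 2000).
#'
#' @param hap_a,hap_b 0/1 haplotype vectors over the same sites.
#' @param site_positions Sorted 0-based site positions.
#' @param W Window width (bp).
#' @param L Sequence length (bp).
#' @return Integer vector of length `L`.
#' @export
brute_force_window_counts <- function(hap_a, hap_b, site_positions, W, L) {
  het <- site_positions[hap_a != hap_b]
  lo <- W %/% 2L
  vapply(seq.int(0L, L - 1L), function(i) {
    sum(het >= i - lo & het < i + W - lo)
  }, 0L)
}

#' Naive heterozygosity-modified recombination probabilities (reference)
#'
#' Literal evaluation of `r_i = r0_i * (1 - E*h/W)` with clamping at zero,
#' using [brute_force_window_counts()] for `h`.
#'
#' @param hap_a,hap_b 0/1 haplotype vectors.
#' @param site_positions Sorted 0-based site positions.
#' @param r0 Baseline per-position recombination probabilities (length `L`).
#' @param E Suppression factor.
#' @param W Window width (bp).
#' @return Numeric vector `r_i` of length `L`.
#' @export
brute_force_meiosis_probs <- function(hap_a, hap_b, site_positions, r0,
                                      E, W) {
  L <- length(r0)
  h <- brute_force_window_counts(hap_a, hap_b, site_positions, W, L)
  r0 * pmax(0, 1 - E * h / W)
}

#' Neutral autosomal control run
#'
#' Runs the same generation loop with autosomal transmission (each parent
#' transmits either haplotype with probability 1/2; the SD locus and sexes
#' play no role) and returns the mean pairwise diversity per site averaged
#' over all records past the burn-in.  At mutation-drift equilibrium the
#' expectation is `theta = 4*N*mu` per site, the yardstick against which the
#' X- and Y-linked diversities are set (3/4 and 1/4 of the autosomal value).
#'
#' @param params A [sim_params()] object.
#' @param burn_in Generations to discard before averaging (default `20*N`,
#'   several coalescent timescales).
#' @param seed Seed (default `params$seed`).
#' @return Mean pairwise diversity per site (a single number).
#' @export
autosomal_control_run <- function(params, burn_in = 20 * params$N,
                                  seed = params$seed) {
  stopifnot(inherits(params, "sim_params"),
            params$generations > burn_in)
  res <- run(params, record_profiles = "none", inheritance = "autosomal",
             seed = seed)
  rec <- res$records
  mean(rec$pi_all[rec$generation >= burn_in])
}

#' Effective-size ratio experiment: X- and Y-linked vs autosomal diversity
#'
#' Paired sex-linked and autosomal runs under identical neutral conditions
#' (no recombination, no male mutation bias).  For each replicate the
#' sex-linked run contributes the X-pool and Y-pool diversities and the
#' autosomal run the control diversity, each averaged over all records past
#' the burn-in; ratios of replicate-mean diversities estimate the relative
#' effective sizes, with expectations 3/4 (X) and 1/4 (Y).
#'
#' @param N,L,mu Population size, sequence length, mutation rate.
#' @param n_replicates Number of replicate pairs.
#' @param generations Run length (must exceed `burn_in`).
#' @param burn_in Generations discarded before averaging (default `20*N`).
#' @param base_seed Base seed; replicate seeds are derived from it.
#' @return List with per-replicate means `pi_x`, `pi_y`, `pi_auto` and the
#'   summary ratios `x_auto_ratio`, `y_auto_ratio`.
#' @export
effective_size_ratios <- function(N = 50, L = 2000, mu = 1e-4,
                                  n_replicates = 100,
                                  generations = 3000,
                                  burn_in = 20 * N,
                                  base_seed = 1) {
  stopifnot(generations > burn_in)
  p <- sim_params(N = N, L = L, mu = mu, r = 0, E = 30, W = min(1000, L),
                  generations = generations, record_interval = 100,
                  n_replicates = n_replicates, seed = as.integer(base_seed))
  post <- function(rec, col) mean(rec[[col]][rec$generation >= burn_in])
  pi_x <- pi_y <- pi_auto <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    sexed <- run(p, record_profiles = "none", inheritance = "sex_linked",
                 seed = p$seed + 2L * (i - 1L))
    auto <- run(p, record_profiles = "none", inheritance = "autosomal",
                seed = p$seed + 2L * (i - 1L) + 1L)
    pi_x[i] <- post(sexed$records, "pi_x")
    pi_y[i] <- post(sexed$records, "pi_y")
    pi_auto[i] <- post(auto$records, "pi_all")
  }
  list(pi_x = pi_x, pi_y = pi_y, pi_auto = pi_auto,
       x_auto_ratio = mean(pi_x) / mean(pi_auto),
       y_auto_ratio = mean(pi_y) / mean(pi_auto))
}
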