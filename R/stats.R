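#' Size of the non-recombining region
#'
#' The NRR is the maximal contiguous interval containing the SD position in
#' which the heterozygosity-modified recombination probability `r_i` equals
#' zero for every in-scope meiosis (each individual evaluated against its own
#' sex's baseline vector).  Scope `"males_only"` (default in [sim_params()])
#' requires all male meioses to be non-recombining; `"all_individuals"` adds
#' the female meioses.  Returns 0 when the SD position itself can recombine
#' in any in-scope individual.
#'
#' This is a direct dense-vector implementation used as the reference; the
#' engine computes the same quantity sparsely during [run()].
#'
#' @param pop A `sim_population`.
#' @param landscape A [make_landscape()] object.
#' @param params A [sim_params()] object (supplies `E`, `W`, `nrr_scope`).
#' @return NRR size in bp.
#' @export
nrr_size <- function(pop, landscape, params) {
  stopifnot(inherits(pop, "sim_population"),
            inherits(landscape, "sim_landscape"),
            inherits(params, "sim_params"))
  if (is.na(pop$sd_position)) return(NA_integer_)
  L <- pop$L
  sd_i <- pop$sd_position + 1L            # 1-based index
  ok <- rep(TRUE, L)
  for (ind in seq_along(pop$sexes)) {
    sexi <- pop$sexes[ind]
    if (params$nrr_scope == "males_only" && sexi != "male") next
    r0 <- if (sexi == "male") landscape$male_r0 else landscape$female_r0
    h <- window_count_profile(het_positions(pop, ind), params$W, L)
    ri <- modified_recomb_probs(r0, h, params$E, params$W)
    ok <- ok & (ri == 0)
    if (!ok[sd_i]) return(0L)
  }
  if (!ok[sd_i]) return(0L)
  lo <- sd_i
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- sd_i
  while (hi < L && ok[hi + 1L]) hi <- hi + 1L
  as.integer(hi - lo + 1L)
}

#' Mean within-individual sequence divergence, by sex
#'
#' `dxy` is the mean over males of the proportion of the `L` simulated
#' positions at which the individual's two haplotypes (an X--Y pair) differ;
#' `dxx` is the same over females (X--X pairs).  The SD site itself counts
#' towards `dxy`.
#'
#' @param pop A `sim_population`.
#' @return Named numeric vector `c(dxx = , dxy = )`.
#' @export
divergence_means <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  n_het <- vapply(seq_along(pop$sexes),
                  function(i) length(het_positions(pop, i)), 0L)
  male <- pop$sexes == "male"
  if (!any(male) || !any(!male))
    stop("both sexes must be present to compute dXX and dXY", call. = FALSE)
  c(dxx = mean(n_het[!male]) / pop$L,
    dxy = mean(n_het[male]) / pop$L)
}

#' Per-position male-female FST profile
#'
#' Hudson-style estimator from haplotype allele frequencies: with derived
#' allele frequency `p_m` among male-carried haplotypes and `p_f` among
#' female-carried haplotypes, between-group heterozygosity
#' `Hb = p_m(1-p_f) + p_f(1-p_m)`, within-group
#' `Hw = p_m(1-p_m) + p_f(1-p_f)`, and `FST = (Hb - Hw)/Hb`, defined as 0
#' where `Hb = 0`.  At the SD position (`p_m = 1/2`, `p_f = 0`) this gives
#' `FST = 0.5`.
#'
#' @param pop A `sim_population`.
#' @return Numeric vector of length `L` (zero at monomorphic positions).
#' @export
fst_profile <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  male_ind <- pop$sexes == "male"
  if (!any(male_ind) || !any(!male_ind))
    stop("both sexes must be present to compute FST", call. = FALSE)
  hap_sex <- rep(pop$sexes, each = 2L)
  m <- pop$haplotypes[hap_sex == "male", , drop = FALSE]
  f <- pop$haplotypes[hap_sex == "female", , drop = FALSE]
  p_m <- colMeans(m)
  p_f <- colMeans(f)
  hb <- p_m * (1 - p_f) + p_f * (1 - p_m)
  hw <- p_m * (1 - p_m) + p_f * (1 - p_f)
  fst_sites <- ifelse(hb > 0, (hb - hw) / hb, 0)
  out <- numeric(pop$L)
  out[pop$site_positions + 1L] <- fst_sites
  out
}

#' Mean pairwise nucleotide diversity within a haplotype pool
#'
#' Mean number of pairwise differences per site across all haplotype pairs
#' in the pool.  Pools: `"all"` (every haplotype), `"X"` (female-carried
#' plus male X haplotypes), `"Y"` (male Y haplotypes).  Sites fixed within
#' the pool (such as the SD allele within each pool) contribute nothing.
#'
#' @param pop A `sim_population`.
#' @param pool `"all"`, `"X"`, or `"Y"`.
#' @return Mean pairwise diversity per site.
#' @export
pairwise_diversity <- function(pop, pool = c("all", "X", "Y")) {
  stopifnot(inherits(pop, "sim_population"))
  pool <- match.arg(pool)
  keep <- switch(pool,
    all = rep(TRUE, nrow(pop$haplotypes)),
    X = sd_alleles(pop) == "X",
    Y = sd_alleles(pop) == "Y"
  )
  n <- sum(keep)
  if (n < 2)
    stop("pool `", pool, "` has fewer than two haplotypes", call. = FALSE)
  cnt <- colSums(pop$haplotypes[keep, , drop = FALSE])
  sum(cnt * (n - cnt)) / (n * (n - 1) / 2) / pop$L
}

#' Aggregate replicate time series into mean and standard deviation tables
#'
#' Accepts either a `sim_replicates` object or a data frame in the layout of
#' `timeseries.tsv` (a `replicate` column plus per-record statistics).
#'
#' @param x A [run_replicates()] result, a data frame, or a path to a
#'   `timeseries.tsv` file.
#' @return Tibble with one row per generation and `_mean`/`_sd` columns for
#'   every statistic.
#' @export
summarize_replicates <- function(x) {
  if (inherits(x, "sim_replicates")) return(x$summary)
  if (is.character(x)) x <- read.delim(x, sep = "\t")
  stopifnot(is.data.frame(x), "generation" %in% names(x))
  stat_cols <- setdiff(names(x), c("replicate", "generation"))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$generation),
    dplyr::across(dplyr::all_of(stat_cols),
                  list(mean = ~mean(.x), sd = ~sd(.x))),
    .groups = "drop"
  )
}
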