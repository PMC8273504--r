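#' Construct a population object
#'
#' Low-level constructor used by [init_population()], [step_generation()] and
#' the test suite.  Haplotypes are stored as a `2N x S` 0/1 integer matrix
#' over the current segregating sites (1 = derived allele); individual `j`
#' owns rows `2j-1` and `2j`.  At the SD position the derived allele is the
#' male-determining Y allele.
#'
#' @param haplotypes Integer 0/1 matrix, `2N` rows, one column per
#'   segregating site.
#' @param site_positions Sorted 0-based bp positions of the segregating
#'   sites (one per haplotype column).
#' @param sexes Character vector of length `N`, entries `"female"`/`"male"`.
#' @param sd_position 0-based position of the SD nucleotide, or `NA` for an
#'   autosomal (control) population.
#' @param L Sequence length in bp.
#' @param generation Generation index of this population.
#' @return An object of class `sim_population`.
#' @export
new_population <- function(haplotypes, site_positions, sexes, sd_position,
                           L, generation = 0L) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  site_positions <- as.integer(site_positions)
  stopifnot(
    ncol(haplotypes) == length(site_positions),
    nrow(haplotypes) == 2L * length(sexes),
    !is.unsorted(site_positions, strictly = TRUE),
    all(haplotypes %in% c(0L, 1L)),
    all(sexes %in% c("female", "male"))
  )
  pop <- list(
    haplotypes = haplotypes,
    site_positions = site_positions,
    sexes = as.character(sexes),
    sd_position = if (is.na(sd_position)) NA_integer_
                  else as.integer(sd_position),
    L = as.integer(L),
    generation = as.integer(generation)
  )
  class(pop) <- "sim_population"
  pop
}

#' Initial population: monomorphic except at the SD locus
#'
#' The simulated populations start with no polymorphism other than the SD
#' nucleotide: every male carries one Y haplotype (derived allele at the SD
#' position) and one X, every female two X haplotypes.  Under
#' `sex_ratio_mode = "fixed_equal"` exactly `N/2` individuals of each sex are
#' created; under `"binomial"` each individual's sex is an independent coin
#' flip (redrawn in the rare event a sex is absent entirely).
#'
#' @param params A [sim_params()] object.
#' @param rng_seed Integer seed; the call is reproducible given the seed.
#' @return A `sim_population` at generation 0 with the SD site as its single
#'   segregating site.
#' @examples
#' pop <- init_population(sim_params(N = 10, L = 1000), rng_seed = 1)
#' table(pop$sexes)
#' @export
init_population <- function(params, rng_seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(rng_seed)
  N <- params$N
  if (params$sex_ratio_mode == "fixed_equal") {
    sexes <- sample(rep(c("male", "female"), each = N / 2L))
  } else {
    repeat {
      sexes <- sample(c("female", "male"), N, replace = TRUE)
      if (length(unique(sexes)) == 2L) break
    }
  }
  # one segregating column: the SD site; males are X/Y (first haplotype = Y)
  hap <- matrix(0L, nrow = 2L * N, ncol = 1L)
  hap[2L * which(sexes == "male") - 1L, 1L] <- 1L
  new_population(hap, params$sd_position, sexes, params$sd_position,
                 params$L, generation = 0L)
}

#' Which haplotypes carry the Y allele?
#'
#' @param pop A `sim_population`.
#' @return Character vector, one entry (`"X"` or `"Y"`) per haplotype row.
#'   For autosomal populations, all `"X"`.
#' @export
sd_alleles <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  out <- rep("X", nrow(pop$haplotypes))
  if (!is.na(pop$sd_position)) {
    j <- match(pop$sd_position, pop$site_positions)
    if (!is.na(j)) out[pop$haplotypes[, j] == 1L] <- "Y"
  }
  out
}

#' Heterozygous site positions of one individual
#'
#' @param pop A `sim_population`.
#' @param individual Individual index in `1..N`.
#' @return Sorted 0-based positions at which the individual's two haplotypes
#'   differ.
#' @export
het_positions <- function(pop, individual) {
  stopifnot(inherits(pop, "sim_population"))
  a <- pop$haplotypes[2L * individual - 1L, ]
  b <- pop$haplotypes[2L * individual, ]
  pop$site_positions[a != b]
}

#' Per-site derived allele counts
#'
#' @param pop A `sim_population`.
#' @return Integer vector of derived-allele counts (over all `2N`
#'   haplotypes), one per segregating site.
#' @export
derived_counts <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  as.integer(colSums(pop$haplotypes))
}

#' @export
print.sim_population <- function(x, ...) {
  N <- length(x$sexes)
  cat(sprintf("Population of %d diploids at generation %d (%d bp)\n",
              N, x$generation, x$L))
  cat(sprintf("  %d segregating sites; %d males, %d females\n",
              length(x$site_positions),
              sum(x$sexes == "male"), sum(x$sexes == "female")))
  if (!is.na(x$sd_position))
    cat(sprintf("  SD locus at %d (%d Y haplotypes)\n",
                x$sd_position, sum(sd_alleles(x) == "Y")))
  invisible(x)
}
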