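#' Sex-specific mutation rates under male mutation bias
#'
#' Splits the sex-averaged per-site rate `mu` into male and female rates
#' whose ratio is `mmb` and whose arithmetic mean is exactly `mu`:
#' `mu_male = 2*mmb*mu/(1 + mmb)`, `mu_female = 2*mu/(1 + mmb)`.
#'
#' @param mu Sex-averaged per-site per-gamete mutation rate.
#' @param mmb Male/female rate ratio, `>= 1`.
#' @return Named numeric vector `c(mu_male = , mu_female = )`.
#' @examples
#' sexed_mutation_rates(7.5e-6, mmb = 10)
#' @export
sexed_mutation_rates <- function(mu, mmb) {
  if (!is.numeric(mu) || mu <= 0)
    stop("`mu` must be positive", call. = FALSE)
  if (!is.numeric(mmb) || mmb < 1)
    stop("`mmb` must be >= 1", call. = FALSE)
  c(mu_male = 2 * mmb * mu / (1 + mmb),
    mu_female = 2 * mu / (1 + mmb))
}

#' Mutation model
#'
#' @param mu Sex-averaged mutation rate.
#' @param mmb Male mutation bias (>= 1).
#' @param collision_policy `"reallocate"` or `"discard"`: what happens to a
#'   mutation drawn at an already polymorphic position.
#' @return An object of class `mutation_model` with fields `mu_male`,
#'   `mu_female`, `collision_policy`.
#' @export
mutation_model <- function(mu, mmb = 1,
                           collision_policy = c("reallocate", "discard")) {
  collision_policy <- match.arg(collision_policy)
  rates <- sexed_mutation_rates(mu, mmb)
  structure(
    list(mu_male = unname(rates["mu_male"]),
         mu_female = unname(rates["mu_female"]),
         collision_policy = collision_policy),
    class = "mutation_model"
  )
}

#' Place new neutral mutations on a gamete
#'
#' The number of new mutations is Poisson with mean `mu_sex * L`; positions
#' are uniform on `[0, L)`.  A draw landing on a currently polymorphic
#' position (including the SD nucleotide, which is always polymorphic) is
#' redrawn under `"reallocate"` or dropped under `"discard"`, so every site
#' stays biallelic.  Each accepted mutation creates a new segregating site
#' carried by this gamete only.
#'
#' @param gamete 0/1 haplotype vector over `site_positions`.
#' @param site_positions Sorted 0-based positions the gamete is aligned on.
#' @param mu_sex Per-site mutation rate of the transmitting parent's sex.
#' @param L Sequence length (bp).
#' @param polymorphic_positions Integer positions currently segregating in
#'   the parental population (collision targets).
#' @param policy `"reallocate"` or `"discard"`.
#' @return List with `haplotype` and `site_positions` (both extended by the
#'   new sites, in position order) and `new_positions` (the accepted
#'   mutation positions).
#' @export
mutate_gamete <- function(gamete, site_positions, mu_sex, L,
                          polymorphic_positions,
                          policy = c("reallocate", "discard")) {
  policy <- match.arg(policy)
  stopifnot(length(gamete) == length(site_positions), mu_sex >= 0)
  n <- rpois(1L, mu_sex * L)
  new_pos <- integer(0)
  if (n > 0L) {
    blocked <- as.integer(polymorphic_positions)
    if (policy == "reallocate" && length(blocked) >= L)
      stop("all positions are polymorphic; cannot reallocate", call. = FALSE)
    for (k in seq_len(n)) {
      repeat {
        pos <- as.integer(floor(runif(1L) * L))
        hit <- pos %in% blocked || pos %in% new_pos
        if (!hit) {
          new_pos <- c(new_pos, pos)
          break
        }
        if (policy == "discard") break
      }
    }
  }
  if (length(new_pos) > 0L) {
    all_pos <- c(site_positions, new_pos)
    all_hap <- c(as.integer(gamete), rep(1L, length(new_pos)))
    o <- order(all_pos)
    list(haplotype = all_hap[o], site_positions = as.integer(all_pos[o]),
         new_positions = sort(new_pos))
  } else {
    list(haplotype = as.integer(gamete),
         site_positions = as.integer(site_positions),
         new_positions = integer(0))
  }
}
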