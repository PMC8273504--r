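#' Sliding-window heterozygosity counts
#'
#' For every position `i` in `[0, L)`, counts the sites at which the two
#' haplotypes differ that fall inside the window of width `W` centred on `i`
#' (the half-open interval `[i - floor(W/2), i + W - floor(W/2))`, clipped to
#' the sequence).  This is the quantity `h` entering the recombination
#' modifier `r_i = r0_i * (1 - E*h/W)`.
#'
#' Implemented as a difference array over the sparse heterozygous-site
#' positions, O(k + L) per meiosis.
#'
#' @param hap_a,hap_b Integer 0/1 vectors over the same segregating sites.
#' @param site_positions Sorted 0-based positions of those sites.
#' @param W Window width (bp).
#' @param L Sequence length (bp).
#' @return Integer vector of length `L`.
#' @examples
#' h <- het_window_counts(c(0, 1), c(1, 1), c(100, 400), W = 100, L = 1000)
#' sum(h)  # 100: one heterozygous site seen by exactly W windows (interior)
#' @export
het_window_counts <- function(hap_a, hap_b, site_positions, W, L) {
  stopifnot(length(hap_a) == length(hap_b),
            length(hap_a) == length(site_positions))
  het <- site_positions[hap_a != hap_b]
  window_count_profile(het, W, L)
}

# difference-array profile of window membership counts for a set of
# heterozygous positions; windows are [i - lo, i + W - lo) with lo = floor(W/2),
# so site j is seen by targets i in [j - W + lo + 1, j + lo].
window_count_profile <- function(het_pos, W, L) {
  W <- as.integer(W); L <- as.integer(L)
  counts <- integer(L)
  if (length(het_pos) == 0L) return(counts)
  lo <- W %/% 2L
  start <- pmax(het_pos - W + lo + 1L, 0L)
  end <- pmin(het_pos + lo + 1L, L)        # half-open end
  keep <- start < end
  d <- integer(L + 1L)
  for (k in which(keep)) {
    d[start[k] + 1L] <- d[start[k] + 1L] + 1L
    d[end[k] + 1L] <- d[end[k] + 1L] - 1L
  }
  cumsum(d[seq_len(L)])
}

#' Heterozygosity-modified recombination probabilities
#'
#' Applies the linear suppression rule `r_i = r0_i * (1 - E*h/W)`, clamped at
#' zero: with `E = 30` and `W = 1000` a single heterozygous site lowers the
#' local baseline by 3%, and the probability reaches zero once local
#' divergence `h/W` reaches `1/E`.
#'
#' @param r0 Baseline per-position recombination probabilities.
#' @param h_counts Window heterozygosity counts ([het_window_counts()]).
#' @param E Suppression factor.
#' @param W Window width (bp).
#' @return Numeric vector `r_i` of the same length, `0 <= r_i <= r0`.
#' @examples
#' modified_recomb_probs(1e-7, h_counts = 1, E = 30, W = 1000)  # 9.7e-8
#' @export
modified_recomb_probs <- function(r0, h_counts, E, W) {
  stopifnot(length(r0) == length(h_counts))
  r0 * pmax(0, 1 - E * h_counts / W)
}

#' Assemble one individual's meiosis context
#'
#' Bundles the parent's haplotype pair with its sex-specific baseline vector
#' and the heterozygosity-modified per-position recombination probabilities.
#'
#' @param hap_a,hap_b The parent's two haplotypes (0/1 over segregating
#'   sites).
#' @param site_positions Sorted 0-based site positions.
#' @param sex `"female"` or `"male"` (selects the landscape vector).
#' @param landscape A [make_landscape()] object.
#' @param E,W Suppression factor and window width.
#' @return An object of class `meiosis_context`: list with `hap_a`, `hap_b`,
#'   `site_positions`, `sex`, `r0`, `h_counts`, `r_i`.
#' @export
meiosis_context <- function(hap_a, hap_b, site_positions, sex, landscape,
                            E, W) {
  stopifnot(inherits(landscape, "sim_landscape"),
            sex %in% c("female", "male"))
  r0 <- if (sex == "male") landscape$male_r0 else landscape$female_r0
  h <- het_window_counts(hap_a, hap_b, site_positions, W, landscape$L)
  structure(
    list(hap_a = as.integer(hap_a), hap_b = as.integer(hap_b),
         site_positions = as.integer(site_positions), sex = sex,
         r0 = r0, h_counts = h,
         r_i = modified_recomb_probs(r0, h, E, W)),
    class = "meiosis_context"
  )
}

#' Sample crossover breakpoints
#'
#' Each position is a breakpoint independently with probability `r_i[pos]`
#' (no crossover interference).  Suppression therefore lowers the total
#' crossover rate rather than redistributing events.  A breakpoint at
#' position `i` means the gamete switches source haplotype for all positions
#' `>= i`.
#'
#' @param r_i Per-position recombination probabilities (length `L`).
#' @return Sorted integer vector of 0-based breakpoint positions (often
#'   empty: the expected count is `sum(r_i)`).
#' @export
sample_crossovers <- function(r_i) {
  which(runif(length(r_i)) < r_i) - 1L
}

#' Form a gamete from a meiosis
#'
#' The gamete copies `hap_a` or `hap_b` (starting haplotype chosen with
#' probability 1/2 unless `start` is given) up to the first breakpoint and
#' alternates source at each subsequent breakpoint.  For a male meiosis the
#' returned `sd_allele` says whether the gamete carries the Y (derived) or X
#' (ancestral) allele at the SD position.
#'
#' @param ctx A [meiosis_context()] (or any list with `hap_a`, `hap_b`,
#'   `site_positions`).
#' @param breakpoints Sorted 0-based breakpoint positions.
#' @param sd_position SD position (bp) or `NA`.
#' @param start Optionally force the starting haplotype (`"a"` or `"b"`).
#' @return List with `haplotype` (0/1 vector over `site_positions`) and
#'   `sd_allele` (`"X"`, `"Y"`, or `NA` if `sd_position` is `NA` or not
#'   segregating).
#' @export
form_gamete <- function(ctx, breakpoints, sd_position = NA, start = NULL) {
  if (is.null(start)) start <- sample(c("a", "b"), 1L)
  stopifnot(start %in% c("a", "b"))
  breakpoints <- sort(as.integer(breakpoints))
  # number of breakpoints at or before each site decides the source
  switches <- findInterval(ctx$site_positions, breakpoints - 0.5)
  from_a <- (switches %% 2L == 0L) == (start == "a")
  gam <- ifelse(from_a, ctx$hap_a, ctx$hap_b)
  sd_allele <- NA_character_
  if (!is.na(sd_position)) {
    j <- match(as.integer(sd_position), ctx$site_positions)
    if (!is.na(j)) sd_allele <- if (gam[j] == 1L) "Y" else "X"
  }
  list(haplotype = as.integer(gam), sd_allele = sd_allele)
}
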