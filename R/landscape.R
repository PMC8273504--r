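#' Ancestral recombination landscape
#'
#' Builds the per-sex vectors of baseline per-site recombination
#' probabilities `r0` over all `L` positions.  Whatever the spatial pattern,
#' the global rate -- the mean over both sexes and all positions -- equals
#' `params$r` (to floating-point accuracy), so landscapes differ only in how
#' recombination is distributed, not in how much there is.
#'
#' Shapes (`a` = `params$landscape_amplitude`, `k` = `params$landscape_periods`):
#' \describe{
#'   \item{uniform}{both sexes constant at `r`.}
#'   \item{heterochiasmatic}{female uniform at `r`; male follows a raised
#'     cosine `r * (1 + a*cos(2*pi*i/L))`, highest at the sequence ends and
#'     lowest at the centre where the SD locus sits.}
#'   \item{hotspot_coldspot}{both sexes follow the same sinusoid
#'     `r * (1 + a*sin(2*pi*k*i/L))`, giving `k` hotspot/coldspot cycles.}
#' }
#'
#' @param params A [sim_params()] object.
#' @return An object of class `sim_landscape`: list with numeric vectors
#'   `male_r0` and `female_r0` of length `L`, plus the generating fields.
#' @examples
#' ls <- make_landscape(sim_params(N = 100, L = 1000, r = 1e-7))
#' mean(c(ls$male_r0, ls$female_r0))  # == 1e-7
#' @export
make_landscape <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  L <- params$L
  r <- params$r
  a <- params$landscape_amplitude
  i <- seq.int(0L, L - 1L)
  male <- female <- rep(r, L)
  if (params$landscape_kind == "heterochiasmatic") {
    male <- r * (1 + a * cos(2 * pi * i / L))
    # exact mean preservation: subtract the (tiny) discrete-sum residual
    male <- male - (mean(male) - r)
    male[male < 0] <- 0
  } else if (params$landscape_kind == "hotspot_coldspot") {
    prof <- r * (1 + a * sin(2 * pi * params$landscape_periods * i / L))
    prof <- prof - (mean(prof) - r)
    prof[prof < 0] <- 0
    male <- female <- prof
  }
  structure(
    list(male_r0 = male, female_r0 = female, L = L, r = r,
         kind = params$landscape_kind, amplitude = a,
         periods = params$landscape_periods),
    class = "sim_landscape"
  )
}

#' Per-sex linkage map length in centimorgans
#'
#' The expected number of crossovers per meiosis is the sum of the per-site
#' baseline probabilities; one expected crossover is 100 cM (so the uniform
#' landscape with `r = 1e-7` over 100 kb gives a 1 cM map).
#'
#' @param landscape A `sim_landscape` object.
#' @return Named numeric vector `c(male = , female = )`, in cM.
#' @examples
#' map_length_cM(make_landscape(sim_params(L = 1e5, r = 1e-7)))
#' @export
map_length_cM <- function(landscape) {
  stopifnot(inherits(landscape, "sim_landscape"))
  c(male = 100 * sum(landscape$male_r0),
    female = 100 * sum(landscape$female_r0))
}

#' Export a landscape as a tab-separated table
#'
#' Columns: `position` (0-based), `male_r0`, `female_r0`.
#'
#' @param landscape A `sim_landscape` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  stopifnot(inherits(landscape, "sim_landscape"))
  df <- data.frame(position = seq.int(0L, landscape$L - 1L),
                   male_r0 = landscape$male_r0,
                   female_r0 = landscape$female_r0)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sim_landscape <- function(x, ...) {
  ml <- map_length_cM(x)
  cat(sprintf("%s recombination landscape over %d bp (mean r = %g)\n",
              x$kind, x$L, x$r))
  cat(sprintf("  map length: male %.4g cM, female %.4g cM\n",
              ml[["male"]], ml[["female"]]))
  invisible(x)
}
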