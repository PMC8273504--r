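#' Simulation parameters
#'
#' Construct and validate the full parameter bundle for one simulation run.
#' Coordinates are 0-based over the half-open interval `[0, L)`; the
#' sex-determining (SD) nucleotide sits at position `L/2`.
#'
#' The per-site, per-meiosis baseline recombination probability `r` implies an
#' expected `r * L` crossovers per meiosis, i.e. a linkage map of
#' `100 * r * L` centimorgans.  The population-scaled rates `theta = 4*N*mu`
#' and `rho = 4*N*r` are computed on construction and exposed read-only.
#'
#' @param N Diploid population size (individuals).  Must be even when
#'   `sex_ratio_mode = "fixed_equal"`.
#' @param L Sequence length in bp.
#' @param mu Sex-averaged per-site per-gamete mutation rate, per generation.
#' @param r Per-site baseline recombination probability per meiosis.
#' @param E Suppression factor: each heterozygous site within the window
#'   multiplies the local recombination probability by `(1 - E/W)`.
#' @param W Suppression window width in bp (the window is centred on the
#'   target position).
#' @param mmb Male mutation bias: ratio of male to female mutation rates,
#'   applied while holding the sex-averaged rate at `mu`.  Must be >= 1.
#' @param landscape_kind Ancestral recombination landscape: `"uniform"`,
#'   `"heterochiasmatic"` (male rate low at the centre, high at the ends,
#'   female uniform) or `"hotspot_coldspot"` (shared sinusoid).
#' @param landscape_amplitude Relative amplitude `a` of the non-uniform
#'   landscapes (see [make_landscape()]); must lie in `[0, 1]`.
#' @param landscape_periods Number of full sine periods along the sequence for
#'   the hotspot/coldspot landscape.
#' @param generations Number of generations to simulate.
#' @param record_interval Generations between statistic records.
#' @param n_replicates Default number of replicate runs for
#'   [run_replicates()].
#' @param seed Integer seed for the run (replicate seeds are derived from it).
#' @param collision_policy What to do when a new mutation lands on an already
#'   polymorphic site: `"reallocate"` (redraw until it lands on a monomorphic
#'   position) or `"discard"` (drop it).
#' @param nrr_scope Which meioses must have zero recombination probability for
#'   a position to count as non-recombining: `"males_only"` (default; the
#'   X--Y divergence criterion that allows an NRR to expand) or
#'   `"all_individuals"` (females included; stricter, since female X--X
#'   heterozygosity near the SD stays at neutral background levels).
#' @param sex_ratio_mode `"fixed_equal"` conditions offspring sexes to exactly
#'   `N/2` males and `N/2` females; `"binomial"` lets each offspring's sex
#'   follow its paternal gamete's SD allele unconditionally.
#' @param suppression_semantics `"reduce_total"` (default): heterozygosity
#'   lowers the genome-wide crossover rate.  `"redistribute"`: the total
#'   crossover rate stays at the baseline and event locations are re-drawn
#'   in proportion to the suppressed profile (sensitivity analysis only).
#'
#' @return An object of class `sim_params`: a named list of the validated
#'   fields plus derived `theta` and `rho`.
#' @examples
#' p <- sim_params(N = 100, mu = 7.5e-6, r = 1e-7)
#' p$theta  # 3e-3
#' p$rho    # 4e-5
#' @export
sim_params <- function(N = 100,
                       L = 100000,
                       mu = 7.5e-6,
                       r = 1e-7,
                       E = 30,
                       W = 1000,
                       mmb = 1,
                       landscape_kind = c("uniform", "heterochiasmatic",
                                          "hotspot_coldspot"),
                       landscape_amplitude = 0.9,
                       landscape_periods = 10,
                       generations = 20000,
                       record_interval = 100,
                       n_replicates = 25,
                       seed = 1L,
                       collision_policy = c("reallocate", "discard"),
                       nrr_scope = c("males_only", "all_individuals"),
                       sex_ratio_mode = c("fixed_equal", "binomial"),
                       suppression_semantics = c("reduce_total",
                                                 "redistribute")) {
  landscape_kind <- match.arg(landscape_kind)
  collision_policy <- match.arg(collision_policy)
  nrr_scope <- match.arg(nrr_scope)
  sex_ratio_mode <- match.arg(sex_ratio_mode)
  suppression_semantics <- match.arg(suppression_semantics)

  check_scalar <- function(x, nm, integerish = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    if (integerish && abs(x - round(x)) > 1e-8)
      stop("`", nm, "` must be a whole number", call. = FALSE)
    as.numeric(x)
  }
  N <- check_scalar(N, "N", integerish = TRUE)
  L <- check_scalar(L, "L", integerish = TRUE)
  mu <- check_scalar(mu, "mu")
  r <- check_scalar(r, "r")
  E <- check_scalar(E, "E")
  W <- check_scalar(W, "W", integerish = TRUE)
  mmb <- check_scalar(mmb, "mmb")
  landscape_amplitude <- check_scalar(landscape_amplitude,
                                      "landscape_amplitude")
  landscape_periods <- check_scalar(landscape_periods, "landscape_periods",
                                    integerish = TRUE)
  generations <- check_scalar(generations, "generations", integerish = TRUE)
  record_interval <- check_scalar(record_interval, "record_interval",
                                  integerish = TRUE)
  n_replicates <- check_scalar(n_replicates, "n_replicates",
                               integerish = TRUE)
  seed <- check_scalar(seed, "seed", integerish = TRUE)

  fail <- function(nm, why) {
    stop("invalid `", nm, "`: ", why, call. = FALSE)
  }
  if (N < 2) fail("N", "need at least 2 individuals")
  if (sex_ratio_mode == "fixed_equal" && N %% 2 != 0)
    fail("N", "must be even under sex_ratio_mode = \"fixed_equal\"")
  if (L < 2) fail("L", "sequence must be at least 2 bp")
  if (mu <= 0 || mu >= 1) fail("mu", "must satisfy 0 < mu < 1")
  if (r < 0 || r >= 1) fail("r", "must satisfy 0 <= r < 1")
  if (E < 0) fail("E", "must be >= 0")
  if (W < 1 || W > L) fail("W", "must satisfy 1 <= W <= L")
  if (mmb < 1) fail("mmb", "male mutation bias must be >= 1")
  if (landscape_amplitude < 0 || landscape_amplitude > 1)
    fail("landscape_amplitude", "must lie in [0, 1]")
  if (landscape_periods < 1) fail("landscape_periods", "must be >= 1")
  if (generations < 0) fail("generations", "must be >= 0")
  if (record_interval < 1) fail("record_interval", "must be >= 1")
  if (n_replicates < 1) fail("n_replicates", "must be >= 1")
  if (abs(seed) >= 2^31) fail("seed", "must fit in a 32-bit integer")

  p <- list(
    N = as.integer(N), L = as.integer(L), mu = mu, r = r, E = E,
    W = as.integer(W), mmb = mmb,
    landscape_kind = landscape_kind,
    landscape_amplitude = landscape_amplitude,
    landscape_periods = as.integer(landscape_periods),
    generations = as.integer(generations),
    record_interval = as.integer(record_interval),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    collision_policy = collision_policy,
    nrr_scope = nrr_scope,
    sex_ratio_mode = sex_ratio_mode,
    suppression_semantics = suppression_semantics,
    sd_position = as.integer(L %/% 2),
    theta = 4 * N * mu,
    rho = 4 * N * r
  )
  class(p) <- "sim_params"
  p
}

#' Build simulation parameters from a flat configuration mapping
#'
#' Accepts a named list (or a YAML/JSON file path) whose keys match
#' [sim_params()] argument names.  Unknown keys are rejected.  A configuration
#' may alternatively specify the population-scaled rates `theta` and/or `rho`
#' in place of `mu` and `r`; they are converted via `mu = theta/(4N)` and
#' `r = rho/(4N)`.
#'
#' @param config Named list, or path to a YAML or JSON file containing one.
#' @return A validated `sim_params` object.
#' @examples
#' make_params(list(N = 100, mu = 7.5e-6, r = 1e-7))
#' make_params(list(N = 100, theta = 3e-3, rho = 4e-5))
#' @export
make_params <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  if (!is.list(config))
    stop("`config` must be a named list or a file path", call. = FALSE)
  if (length(config) > 0 &&
      (is.null(names(config)) || any(names(config) == "")))
    stop("all configuration entries must be named", call. = FALSE)

  nm <- names(config)
  known <- c(names(formals(sim_params)), "theta", "rho")
  unknown <- setdiff(nm, known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  N <- if ("N" %in% nm) config$N else formals(sim_params)$N
  if ("theta" %in% nm) {
    if ("mu" %in% nm)
      stop("specify either `mu` or `theta`, not both", call. = FALSE)
    config$mu <- config$theta / (4 * N)
    config$theta <- NULL
  }
  if ("rho" %in% nm) {
    if ("r" %in% nm)
      stop("specify either `r` or `rho`, not both", call. = FALSE)
    config$r <- config$rho / (4 * N)
    config$rho <- NULL
  }
  do.call(sim_params, config)
}

read_config_file <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a parameter bundle to a YAML configuration file
#'
#' The written file round-trips through [make_params()].
#'
#' @param params A `sim_params` object.
#' @param path Output file path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  cfg <- unclass(params)
  cfg$theta <- NULL
  cfg$rho <- NULL
  cfg$sd_position <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Population-scaled mutation and recombination rates
#'
#' @param params A `sim_params` object.
#' @return Named numeric vector with `theta = 4*N*mu` and `rho = 4*N*r`.
#' @examples
#' theta_rho(sim_params(N = 100, mu = 7.5e-6, r = 1e-7))
#' @export
theta_rho <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  c(theta = params$theta, rho = params$rho)
}

#' Rescale a parameter set for desk-scale runs
#'
#' Reduces sequence length and run length by `scale` while leaving the
#' per-site rates `mu` and `r` (and the window `W`) untouched, so that the
#' local dynamics around the SD locus are preserved.  The SD position moves to
#' the new `L/2`.
#'
#' @param params A `sim_params` object.
#' @param scale Scale factor in `(0, 1]`.
#' @param n_replicates Optional replicate count for the scaled set (defaults
#'   to 10 when `scale < 1`, mirroring the desk-scale presets).
#' @return A new `sim_params` object.
#' @export
scale_params <- function(params, scale, n_replicates = NULL) {
  stopifnot(inherits(params, "sim_params"), scale > 0, scale <= 1)
  if (is.null(n_replicates)) {
    n_replicates <- if (scale < 1) 10L else params$n_replicates
  }
  upd <- unclass(params)
  upd$L <- max(as.integer(round(params$L * scale)), params$W)
  upd$generations <- as.integer(round(params$generations * scale))
  upd$n_replicates <- as.integer(n_replicates)
  upd$theta <- upd$rho <- upd$sd_position <- NULL
  do.call(sim_params, upd)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (nrrsim)\n")
  cat(sprintf("  N = %d diploids, L = %d bp, SD at %d\n",
              x$N, x$L, x$sd_position))
  cat(sprintf("  mu = %g (mmb = %g), r = %g, E = %g, W = %d\n",
              x$mu, x$mmb, x$r, x$E, x$W))
  cat(sprintf("  theta = 4N*mu = %g, rho = 4N*r = %g, map = %g cM\n",
              x$theta, x$rho, 100 * x$r * x$L))
  cat(sprintf("  landscape = %s, generations = %d (record every %d)\n",
              x$landscape_kind, x$generations, x$record_interval))
  cat(sprintf("  replicates = %d, seed = %d, collisions = %s\n",
              x$n_replicates, x$seed, x$collision_policy))
  cat(sprintf("  nrr_scope = %s, sex ratio = %s, suppression = %s\n",
              x$nrr_scope, x$sex_ratio_mode, x$suppression_semantics))
  invisible(x)
}
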