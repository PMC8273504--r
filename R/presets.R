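#' The seven published simulation sets
#'
#' Machine-readable table of the parameter sets used in the original
#' parameter sweeps.  Each row is one set: the focal (varied) parameter is
#' given as a grid in `expand_sweep()`; the fixed values are listed here.
#' All sets share `N`-scaled anchors theta = 3e-3 and rho = 4e-5 at
#' `N = 100`, `mu = 7.5e-6`, `r = 1e-7` (a 1 cM map over 100 kb) except
#' where the set varies them.
#'
#' @return Tibble with one row per set (`set1` ... `set7`).
#' @export
sweep_presets <- function() {
  tibble::tibble(
    preset = paste0("set", 1:7),
    N = c(100, NA, 100, 100, 100, 100, 100),
    generations = c(20000, 20000, 20000, 20000, 10000, 10000, 20000) ,
    mu = c(NA, NA, 7.5e-6, 7.5e-6, 7.5e-6, 7.5e-6, 7.5e-6),
    r = c(NA, NA, 1e-7, 1e-7, 1e-7, 1e-7, 1e-7),
    W = c(1000, 1000, 1000, NA, 1000, 1000, 1000),
    E = c(NA, 10, NA, 10, 10, 10, 10),
    mmb = c(1, 1, 1, 1, 1, 1, NA),
    landscape = c("uniform", "uniform", "uniform", "uniform",
                  "heterochiasmatic", "hotspot_coldspot", "uniform"),
    varied = c("mu, r (E in {10, 30})", "N (theta, rho fixed)", "E", "W",
               "landscape", "landscape", "mmb")
  )
}

#' Sweep specification
#'
#' A preset name expands to the published grid for that simulation set; a
#' custom spec takes explicit `grid` (named list of vectors, crossed) and
#' `fixed` (named list) entries.  `scale` applies [scale_params()] to every
#' point for desk-scale runs (default desk scale is 0.1: 10 kb, one tenth
#' of the generations, 10 replicates).
#'
#' @param preset `"set1"` ... `"set7"`, or `"custom"`.
#' @param grid Named list of parameter grids (crossed). For presets, the
#'   published grid is used unless overridden here.
#' @param fixed Named list of fixed parameter overrides.
#' @param scale Scale factor in `(0, 1]`.
#' @param base_seed Base seed; each grid point gets a derived seed.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(preset = "custom", grid = NULL, fixed = NULL,
                       scale = 1, base_seed = 1) {
  stopifnot(preset %in% c(paste0("set", 1:7), "custom"))
  defaults <- switch(preset,
    set1 = list(
      grid = list(mu = c(1e-6, 2.5e-6, 5e-6, 7.5e-6, 1e-5),
                  r = c(1e-7, 2.5e-7, 5e-7, 1e-6),
                  E = c(10, 30)),
      fixed = list(N = 100, W = 1000, mmb = 1, generations = 20000,
                   landscape_kind = "uniform")),
    set2 = list(
      grid = list(N = c(50, 100, 150, 200)),
      fixed = list(theta = 3e-3, rho = 4e-5, W = 1000, E = 10, mmb = 1,
                   generations = 20000, landscape_kind = "uniform")),
    set3 = list(
      grid = list(E = 6:14),
      fixed = list(N = 100, mu = 7.5e-6, r = 1e-7, W = 1000, mmb = 1,
                   generations = 20000, landscape_kind = "uniform")),
    set4 = list(
      grid = list(W = c(100, 250, 500, 750, 1000)),
      fixed = list(N = 100, mu = 7.5e-6, r = 1e-7, E = 10, mmb = 1,
                   generations = 20000, landscape_kind = "uniform")),
    set5 = list(
      grid = list(landscape_kind = c("uniform", "heterochiasmatic")),
      fixed = list(N = 100, mu = 7.5e-6, r = 1e-7, W = 1000, E = 10,
                   mmb = 1, generations = 10000)),
    set6 = list(
      grid = list(landscape_kind = c("uniform", "hotspot_coldspot")),
      fixed = list(N = 100, mu = 7.5e-6, r = 1e-7, W = 1000, E = 10,
                   mmb = 1, generations = 10000)),
    set7 = list(
      grid = list(mmb = c(1, 2, 5, 10)),
      fixed = list(N = 100, mu = 7.5e-6, r = 1e-7, W = 1000, E = 10,
                   generations = 20000, landscape_kind = "uniform")),
    custom = list(grid = list(), fixed = list())
  )
  if (!is.null(grid)) defaults$grid[names(grid)] <- grid
  if (!is.null(fixed)) defaults$fixed[names(fixed)] <- fixed
  structure(
    list(preset = preset, grid = defaults$grid, fixed = defaults$fixed,
         scale = scale, base_seed = as.integer(base_seed)),
    class = "sweep_spec"
  )
}

#' Expand a sweep into a list of parameter sets
#'
#' Crosses the grid values with the fixed parameters in deterministic
#' ordering (the first grid dimension varies fastest) and assigns each point
#' the derived seed `base_seed + point_index - 1`.  For set 2, `theta` and
#' `rho` are held constant by scaling `mu` and `r` with `N`.
#'
#' @param spec A [sweep_spec()].
#' @return Named list of `sim_params`, one per grid point.
#' @examples
#' length(expand_sweep(sweep_spec("set3")))  # 9 values of E
#' @export
expand_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid_df <- if (length(spec$grid) == 0) data.frame(.point = 1) else
    expand.grid(spec$grid, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid_df))
  for (i in seq_len(nrow(grid_df))) {
    cfg <- spec$fixed
    for (nm in setdiff(names(grid_df), ".point"))
      cfg[[nm]] <- grid_df[[nm]][i]
    cfg$seed <- spec$base_seed + i - 1L
    p <- make_params(cfg)
    if (spec$scale < 1) p <- scale_params(p, spec$scale)
    out[[i]] <- p
    names(out)[i] <- paste(
      vapply(setdiff(names(grid_df), ".point"),
             function(nm) paste0(nm, "=", format(grid_df[[nm]][i])), ""),
      collapse = ",")
  }
  if (length(out) == 1 && identical(names(out), ""))
    names(out) <- spec$preset
  out
}

#' Run a parameter sweep
#'
#' Runs [run_replicates()] for every point of an expanded sweep and collects
#' the final-generation summaries.
#'
#' @param spec A [sweep_spec()].
#' @param n_replicates Replicates per point (default: each point's own
#'   `n_replicates`, i.e. 10 at desk scale).
#' @param record_profiles Passed through to [run_replicates()].
#' @param outdir Optional directory: per-point TSV outputs are written under
#'   `outdir/<point name>/`.
#' @return Tibble with one row per grid point: the varied parameter values,
#'   the final-generation mean and sd of the NRR size and divergences.
#' @export
run_sweep <- function(spec, n_replicates = NULL,
                      record_profiles = "none", outdir = NULL) {
  points <- expand_sweep(spec)
  rows <- vector("list", length(points))
  for (i in seq_along(points)) {
    p <- points[[i]]
    nrep <- if (is.null(n_replicates)) p$n_replicates else n_replicates
    reps <- run_replicates(p, n_replicates = nrep,
                           record_profiles = record_profiles)
    if (!is.null(outdir)) {
      safe <- gsub("[^A-Za-z0-9_.=-]+", "_", names(points)[i])
      write_run_tsv(reps, file.path(outdir, safe))
    }
    last <- reps$summary[nrow(reps$summary), ]
    rows[[i]] <- tibble::tibble(
      point = names(points)[i],
      N = p$N, mu = p$mu, r = p$r, E = p$E, W = p$W, mmb = p$mmb,
      landscape_kind = p$landscape_kind, generations = p$generations,
      n_replicates = nrep,
      nrr_bp_mean = last$nrr_bp_mean, nrr_bp_sd = last$nrr_bp_sd,
      dxx_mean = last$dxx_mean, dxy_mean = last$dxy_mean
    )
  }
  dplyr::bind_rows(rows)
}
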