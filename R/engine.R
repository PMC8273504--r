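# internal: config list handed to the C++ engine
engine_cfg <- function(params, model, sexed, sd_position) {
  list(
    L = params$L, W = params$W, E = params$E,
    mu_male = model$mu_male, mu_female = model$mu_female,
    reallocate = model$collision_policy == "reallocate",
    fixed_equal = params$sex_ratio_mode == "fixed_equal",
    redistribute = params$suppression_semantics == "redistribute",
    sexed = sexed,
    nrr_males_only = params$nrr_scope == "males_only",
    sd = if (is.na(sd_position)) -1L else as.integer(sd_position)
  )
}

pop_to_engine <- function(pop) {
  list(site_positions = pop$site_positions,
       haplotypes = pop$haplotypes,
       sex_codes = as.integer(pop$sexes == "male"),
       generation = pop$generation)
}

pop_from_engine <- function(raw, template) {
  new_population(
    haplotypes = raw$haplotypes,
    site_positions = raw$site_positions,
    sexes = c("female", "male")[raw$sex_codes + 1L],
    sd_position = template$sd_position,
    L = template$L,
    generation = raw$generation
  )
}

#' Advance a population by one generation
#'
#' Random mating with non-overlapping generations: each of the `N` offspring
#' draws a mother and a father uniformly (with replacement), receives one
#' recombinant gamete from each parent's heterozygosity-modified meiosis,
#' and takes its sex from the paternal gamete's SD allele.  Under
#' `sex_ratio_mode = "fixed_equal"` the paternal meiosis is resampled until
#' the SD allele required for an equal sex ratio is transmitted.  New
#' mutations are added to each transmitted gamete at the transmitting
#' parent's sex-specific rate; sites fixed in all `2N` haplotypes are flipped
#' to ancestral and removed.
#'
#' Uses the current R RNG state; call `set.seed()` first for reproducibility.
#'
#' @param pop A `sim_population`.
#' @param params A [sim_params()] object.
#' @param landscape A [make_landscape()] object (defaults to the one implied
#'   by `params`).
#' @param model A [mutation_model()] (defaults to the one implied by
#'   `params`).
#' @return The next-generation `sim_population`.
#' @export
step_generation <- function(pop, params, landscape = make_landscape(params),
                            model = mutation_model(params$mu, params$mmb,
                                                   params$collision_policy)) {
  stopifnot(inherits(pop, "sim_population"), inherits(params, "sim_params"))
  sexed <- !is.na(pop$sd_position)
  cfg <- engine_cfg(params, model, sexed, pop$sd_position)
  raw <- cpp_step(pop_to_engine(pop), cfg, landscape$male_r0,
                  landscape$female_r0)
  pop_from_engine(raw, pop)
}

#' Run one simulation
#'
#' Initializes a population (monomorphic except for the SD nucleotide),
#' iterates [step_generation()] dynamics for `params$generations`
#' generations in compiled code, and records summary statistics every
#' `params$record_interval` generations, starting at generation 0.
#'
#' @param params A [sim_params()] object.
#' @param record_profiles When to record the per-position profiles (FST,
#'   mean modified recombination, heterozygosity): `"final"` (default),
#'   `"none"`, or `"all"` record times.
#' @param inheritance `"sex_linked"` (default) or `"autosomal"`: the
#'   autosomal mode drops the SD locus entirely and lets every parent
#'   transmit either haplotype with probability 1/2 -- the neutral control
#'   used for effective-size comparisons.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return An object of class `sim_run`: list with `params`, `seed`,
#'   `records` (tibble: generation, nrr_bp, dxx, dxy, pi_x, pi_y, pi_all,
#'   n_seg_sites), `profiles` (list of tibbles or `NULL`),
#'   `final_population`, and `rng_draw_count`.
#' @examples
#' p <- sim_params(N = 20, L = 2000, generations = 200, record_interval = 100,
#'                 mu = 1e-4, r = 1e-6, seed = 7)
#' run(p)$records
#' @export
run <- function(params, record_profiles = c("final", "none", "all"),
                inheritance = c("sex_linked", "autosomal"),
                seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  record_profiles <- match.arg(record_profiles)
  inheritance <- match.arg(inheritance)
  set.seed(seed)

  if (inheritance == "sex_linked") {
    pop <- init_population(params, rng_seed = seed)
  } else {
    set.seed(seed)
    N <- params$N
    sexes <- sample(rep(c("male", "female"), length.out = N))
    pop <- new_population(matrix(0L, nrow = 2L * N, ncol = 0L), integer(0),
                          sexes, NA, params$L, generation = 0L)
  }

  landscape <- make_landscape(params)
  model <- mutation_model(params$mu, params$mmb, params$collision_policy)
  cfg <- engine_cfg(params, model, inheritance == "sex_linked",
                    pop$sd_position)

  rec_gens <- seq.int(0L, params$generations, by = params$record_interval)
  prof_gens <- switch(record_profiles,
    none = integer(0),
    final = max(rec_gens),
    all = rec_gens
  )
  raw <- cpp_run(pop_to_engine(pop), cfg, landscape$male_r0,
                 landscape$female_r0, params$generations,
                 params$record_interval, as.integer(prof_gens))

  profiles <- lapply(raw$profiles, function(pr) {
    tibble::tibble(
      generation = pr$generation,
      position = seq.int(0L, params$L - 1L),
      fst = pr$fst,
      mean_ri_male = pr$mean_ri_male,
      mean_ri_female = pr$mean_ri_female,
      het_xy = pr$het_xy,
      het_xx = pr$het_xx
    )
  })

  structure(
    list(
      params = params,
      seed = as.integer(seed),
      inheritance = inheritance,
      records = tibble::as_tibble(raw$records),
      profiles = if (length(profiles)) profiles else NULL,
      final_population = pop_from_engine(raw$population, pop),
      rng_draw_count = raw$rng_draw_count
    ),
    class = "sim_run"
  )
}

#' @export
print.sim_run <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf("Simulation run (%s), seed %d\n", x$inheritance, x$seed))
  cat(sprintf("  %d generations, %d records\n",
              x$params$generations, nrow(x$records)))
  if (x$inheritance == "sex_linked")
    cat(sprintf("  final: NRR = %d bp, dXX = %.3g, dXY = %.3g\n",
                last$nrr_bp, last$dxx, last$dxy))
  invisible(x)
}

#' Run replicate simulations and average the reported statistics
#'
#' Replicate seeds are `base_seed + 0:(n_replicates - 1)`, so the set is
#' deterministic and the replicates distinct.  All recorded statistics are
#' averaged across replicates at each record time (the convention used for
#' every reported quantity: 25 replicates at full scale).
#'
#' @param params A [sim_params()] object.
#' @param n_replicates Number of replicates (default `params$n_replicates`).
#' @param base_seed Base seed (default `params$seed`).
#' @param record_profiles Passed to [run()]; when not `"none"`, the final
#'   FST profile is averaged across replicates into `mean_profile`.
#' @param inheritance Passed to [run()].
#' @return An object of class `sim_replicates`: list with `params`,
#'   `replicates` (per-replicate records, tibble with a `replicate` column),
#'   `summary` (per-generation mean and sd of each statistic),
#'   `mean_profile` (tibble or `NULL`), and `seeds`.
#' @export
run_replicates <- function(params, n_replicates = params$n_replicates,
                           base_seed = params$seed,
                           record_profiles = c("final", "none", "all"),
                           inheritance = c("sex_linked", "autosomal")) {
  stopifnot(inherits(params, "sim_params"), n_replicates >= 1)
  record_profiles <- match.arg(record_profiles)
  inheritance <- match.arg(inheritance)
  seeds <- as.integer(base_seed + seq_len(n_replicates) - 1L)

  runs <- lapply(seq_len(n_replicates), function(i) {
    run(params, record_profiles = record_profiles,
        inheritance = inheritance, seed = seeds[i])
  })

  reps <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    dplyr::mutate(runs[[i]]$records, replicate = i, .before = 1)
  }))

  stat_cols <- c("nrr_bp", "dxx", "dxy", "pi_x", "pi_y", "pi_all",
                 "n_seg_sites")
  summary <- dplyr::summarise(
    dplyr::group_by(reps, .data$generation),
    dplyr::across(dplyr::all_of(stat_cols),
                  list(mean = ~mean(.x), sd = ~sd(.x))),
    .groups = "drop"
  )

  mean_profile <- NULL
  if (record_profiles != "none" && inheritance == "sex_linked") {
    finals <- lapply(runs, function(rn) rn$profiles[[length(rn$profiles)]])
    mean_profile <- finals[[1L]]
    for (col in c("fst", "mean_ri_male", "mean_ri_female",
                  "het_xy", "het_xx")) {
      mean_profile[[col]] <-
        Reduce(`+`, lapply(finals, `[[`, col)) / length(finals)
    }
  }

  structure(
    list(params = params, seeds = seeds, replicates = reps,
         summary = summary, mean_profile = mean_profile),
    class = "sim_replicates"
  )
}

#' @export
print.sim_replicates <- function(x, ...) {
  n <- length(x$seeds)
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("%d replicate runs, base seed %d\n", n, x$seeds[1]))
  cat(sprintf("  final generation %d: mean NRR = %.1f bp (sd %.1f)\n",
              last$generation, last$nrr_bp_mean, last$nrr_bp_sd))
  invisible(x)
}

#' Write run outputs as tab-separated tables
#'
#' Writes `timeseries.tsv` (per-replicate records), `run_meta.tsv` (all
#' parameters and seeds) and, when profiles were recorded,
#' `profiles.tsv` (replicate-averaged final per-position profiles) into
#' `outdir`.
#'
#' @param reps A [run_replicates()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_tsv <- function(reps, outdir) {
  stopifnot(inherits(reps, "sim_replicates"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(reps$replicates, file.path(outdir, "timeseries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- unclass(reps$params)
  meta <- data.frame(key = names(meta),
                     value = vapply(meta, function(v)
                       paste(format(v, digits = 15), collapse = ","), ""),
                     stringsAsFactors = FALSE)
  meta <- rbind(meta, data.frame(
    key = "replicate_seeds", value = paste(reps$seeds, collapse = ",")))
  write.table(meta, file.path(outdir, "run_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reps$mean_profile))
    write.table(reps$mean_profile, file.path(outdir, "profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
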