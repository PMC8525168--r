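# Generation loop, replicate management, seeding and time-series records.

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

census <- function(pop, cfg, generation, f) {
  res_mask <- !pop$disperser
  occ <- tabulate(pop$patch, nbins = cfg$n_patches)
  list(
    record = tibble::tibble(
      generation = generation,
      mean_D = mean_or_na(pop$loci[, "d"]),
      mean_L_R_locus = mean_or_na(pop$loci[, "l_r"]),
      mean_L_D_locus = mean_or_na(pop$loci[, "l_d"]),
      mean_E_R_locus = mean_or_na(pop$loci[, "e_r"]),
      mean_E_D_locus = mean_or_na(pop$loci[, "e_d"]),
      mean_L_expressed_residents = mean_or_na(pop$L[res_mask]),
      mean_L_expressed_dispersers = mean_or_na(pop$L[!res_mask]),
      n_residents = sum(res_mask),
      n_dispersers = sum(!res_mask),
      n_alive = pop_size(pop),
      mean_F = mean_or_na(f)
    ),
    occupancy = occ
  )
}

#' Advance the world by one generation
#'
#' Executes the annual lifecycle in order: develop any newborns (the
#' irreversible phenotype switch), pre-dispersal foraging, the dispersal
#' event with mortality, post-dispersal foraging, fecundity and census
#' (so the census describes the individuals whose fitness is about to be
#' realised), per-patch fitness-proportional recruitment, mutation of the
#' offspring, and the periodic patch-extinction event.
#'
#' @param world World list (offspring not yet developed, or a developed
#'   founder world for the first generation).
#' @param cfg Validated `sim_config`.
#' @param generation_index 1-based generation counter.
#' @param uniform_fitness If `TRUE`, selection is switched off: foraging is
#'   skipped and every occupant recruits with equal weight (used for
#'   neutral-drift checks).
#' @param diagnostics Forwarded to [forage_phase()]; the combined per-phase
#'   diagnostics tibble is returned as `diagnostics`.
#' @return A list with the offspring `world`, the `record` tibble row,
#'   the per-patch `occupancy` counts at census, and `extinct` (TRUE when
#'   the metapopulation is globally extinct).
#' @export
run_generation <- function(world, cfg, generation_index,
                           uniform_fitness = FALSE, diagnostics = FALSE) {
  pop <- world$pop
  if (pop_size(pop) == 0) {
    return(list(world = world, record = NULL, occupancy = NULL, extinct = TRUE))
  }
  if (anyNA(pop$disperser)) pop <- develop_population(pop)
  world$pop <- pop

  diag_acc <- NULL
  if (!uniform_fitness) {
    world <- forage_phase(world, cfg, "before", diagnostics = diagnostics)
    if (diagnostics) diag_acc <- world$diagnostics
  }
  world <- dispersal_phase(world, cfg)$world
  if (!uniform_fitness) {
    world <- forage_phase(world, cfg, "after", diagnostics = diagnostics)
    if (diagnostics) diag_acc <- dplyr::bind_rows(diag_acc, world$diagnostics)
  }

  world$diagnostics <- NULL
  pop <- world$pop
  if (pop_size(pop) == 0) {
    return(list(world = world, record = NULL, occupancy = NULL, extinct = TRUE))
  }

  f <- if (uniform_fitness) rep(1, pop_size(pop)) else {
    fecundity(pop$vtot, pop$L, cfg$learning_cost)
  }
  cen <- census(pop, cfg, generation_index, f)

  kids <- vector("list", cfg$n_patches)
  for (p in seq_len(cfg$n_patches)) {
    in_p <- pop$patch == p
    kids[[p]] <- recruit_patch(pop$loci[in_p, , drop = FALSE], f[in_p],
                               cfg$n_individuals)
  }
  natal <- rep.int(seq_len(cfg$n_patches),
                   vapply(kids, nrow, integer(1)))
  loci <- do.call(rbind, kids)
  loci <- mutate_genotypes(loci, cfg$mutation_prob, cfg$mutation_sd)
  offspring <- new_population(loci, natal, nrow(cfg$resources))
  world$pop <- offspring
  world <- apply_extinction(world, cfg, generation_index)

  list(world = world, record = cen$record, occupancy = cen$occupancy,
       extinct = pop_size(world$pop) == 0, diagnostics = diag_acc)
}

#' Run a full simulation
#'
#' Seeds R's RNG once, initialises a founder world and iterates
#' [run_generation()] for the configured number of generations. The output
#' is fully determined by `(cfg, seed)`. A global extinction truncates the
#' record series and is flagged rather than raised.
#'
#' @param cfg Validated `sim_config`.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param uniform_fitness Switch selection off (see [run_generation()]).
#' @return An object of class `sim_run`: a list with `records` (tibble, one
#'   row per completed generation), `occupancy` (generations x patches
#'   integer matrix), `config`, `seed`, `extinct` and `n_generations_run`.
#' @examples
#' res <- run_simulation(season_preset(2, n_generations = 5), seed = 1)
#' tidy(res)
#' @export
run_simulation <- function(cfg, seed = NULL, uniform_fitness = FALSE) {
  cfg <- validate_config(cfg)
  if (is.null(seed)) seed <- cfg$seed
  seed <- as.integer(seed)
  set.seed(seed)

  world <- init_world(cfg)
  records <- vector("list", cfg$n_generations)
  occupancy <- matrix(0L, nrow = cfg$n_generations, ncol = cfg$n_patches)
  extinct <- FALSE
  g_done <- 0L
  for (g in seq_len(cfg$n_generations)) {
    step <- run_generation(world, cfg, g, uniform_fitness = uniform_fitness)
    world <- step$world
    if (is.null(step$record)) { extinct <- TRUE; break }
    records[[g]] <- step$record
    occupancy[g, ] <- step$occupancy
    g_done <- g
    if (step$extinct) { extinct <- TRUE; break }
  }
  records <- dplyr::bind_rows(records[seq_len(g_done)])
  structure(
    list(records = records,
         occupancy = occupancy[seq_len(g_done), , drop = FALSE],
         config = cfg, seed = seed, extinct = extinct,
         n_generations_run = g_done,
         final_world = world),
    class = "sim_run"
  )
}

#' Run replicate simulations
#'
#' Replicate `k` runs with the derived seed `base_seed + k - 1`, so a base
#' seed fully determines the whole set while replicates remain independent
#' streams.
#'
#' @param cfg Validated `sim_config`.
#' @param n_replicates Number of replicate runs (`>= 1`).
#' @param base_seed Integer base seed.
#' @param uniform_fitness Passed to [run_simulation()].
#' @return A list of `sim_run` objects of length `n_replicates`.
#' @export
run_replicates <- function(cfg, n_replicates = 10, base_seed = 1,
                           uniform_fitness = FALSE) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(k) {
    run_simulation(cfg, seed = base_seed + k - 1L,
                   uniform_fitness = uniform_fitness)
  })
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> %d generation(s) run (seed %d)%s\n",
              x$n_generations_run, x$seed,
              if (x$extinct) " - metapopulation went extinct" else ""))
  if (nrow(x$records)) {
    last <- x$records[nrow(x$records), ]
    cat(sprintf("  final means: D = %.3f, L_R = %.3f, L_D = %.3f\n",
                last$mean_D, last$mean_L_R_locus, last$mean_L_D_locus))
  }
  invisible(x)
}

#' Tidy a simulation run
#'
#' @param x A `sim_run`.
#' @param ... Unused.
#' @return The per-generation record tibble.
#' @method tidy sim_run
#' @export
tidy.sim_run <- function(x, ...) x$records

#' One-row summary of a simulation run
#'
#' @param x A `sim_run`.
#' @param ... Unused.
#' @return A one-row tibble: seed, generations run, extinction flag and the
#'   final generation's locus means.
#' @method glance sim_run
#' @export
glance.sim_run <- function(x, ...) {
  last <- if (nrow(x$records)) x$records[nrow(x$records), ] else
    tibble::tibble(mean_D = NA_real_, mean_L_R_locus = NA_real_,
                   mean_L_D_locus = NA_real_)
  tibble::tibble(
    seed = x$seed, n_generations_run = x$n_generations_run,
    extinct = x$extinct,
    final_mean_D = last$mean_D,
    final_mean_L_R_locus = last$mean_L_R_locus,
    final_mean_L_D_locus = last$mean_L_D_locus
  )
}

#' Write a run's record series to CSV
#'
#' One row per generation with the locus means, expressed-phenotype means,
#' phenotype counts and mean fecundity.
#'
#' @param run A `sim_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  readr::write_csv(run$records, path)
  invisible(path)
}

#' Write a run manifest (config + seed) as JSON
#'
#' Rerunning [run_simulation()] on the manifest's config and seed
#' reproduces the run's CSV byte for byte.
#'
#' @param run A `sim_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  cfg <- run$config
  manifest <- list(
    seed = run$seed,
    extinct = run$extinct,
    n_generations_run = run$n_generations_run,
    config = list(
      world = list(n_patches = cfg$n_patches,
                   n_individuals = cfg$n_individuals,
                   n_generations = cfg$n_generations),
      lifecycle = list(t_before = cfg$t_before, t_after = cfg$t_after,
                       dispersal_mortality = cfg$dispersal_mortality,
                       learning_cost = cfg$learning_cost,
                       competition_factor = cfg$competition_factor),
      mutation = list(mutation_prob = cfg$mutation_prob,
                      mutation_sd = cfg$mutation_sd),
      extinction = list(extinction_every = cfg$extinction_every,
                        extinction_count = cfg$extinction_count),
      resources = cfg$resources,
      patch_types = lapply(cfg$patch_types, function(p) {
        list(patch_type_id = p$patch_type_id,
             abundances = as.list(p$abundances))
      }),
      patch_type_assignment = cfg$patch_type_assignment
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rebuild a configuration from a manifest
#'
#' @param path Path to a JSON manifest written by [write_manifest()].
#' @return A list with elements `cfg` (validated `sim_config`) and `seed`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  c_ <- m$config
  cfg <- validate_config(structure(list(
    n_patches = c_$world$n_patches, n_individuals = c_$world$n_individuals,
    n_generations = c_$world$n_generations,
    t_before = c_$lifecycle$t_before, t_after = c_$lifecycle$t_after,
    dispersal_mortality = c_$lifecycle$dispersal_mortality,
    learning_cost = c_$lifecycle$learning_cost,
    competition_factor = c_$lifecycle$competition_factor,
    mutation_prob = c_$mutation$mutation_prob,
    mutation_sd = c_$mutation$mutation_sd,
    extinction_every = c_$extinction$extinction_every,
    extinction_count = c_$extinction$extinction_count,
    resources = dplyr::bind_rows(lapply(c_$resources, tibble::as_tibble)),
    patch_types = lapply(c_$patch_types, function(p) {
      patch_type_spec(p$patch_type_id, unlist(p$abundances))
    }),
    patch_type_assignment = unlist(c_$patch_type_assignment),
    seed = m$seed
  ), class = "sim_config"))
  list(cfg = cfg, seed = m$seed)
}
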