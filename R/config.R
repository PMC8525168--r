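#' Describe a resource type
#'
#' A resource type is characterised by its fitness value per item `V`, its
#' handling time `H` (the amount of practice needed before items yield their
#' full value; `H = 1` marks a resource that requires no learning) and its
#' detectability `C` (how easily items are found by a fast-moving forager).
#'
#' @param resource_id Integer in 1..10, unique within a configuration.
#' @param value Non-negative fitness value per handled item.
#' @param handling_time Real `>= 1`; `1` means no learning is needed.
#' @param detectability Real in `[0, 1]`.
#' @return A one-row tibble with columns `resource_id`, `value`,
#'   `handling_time`, `detectability`.
#' @examples
#' resource_spec(1, value = 1, handling_time = 1, detectability = 0.5)
#' @export
resource_spec <- function(resource_id, value, handling_time, detectability) {
  tibble::tibble(
    resource_id = as.integer(resource_id),
    value = as.numeric(value),
    handling_time = as.numeric(handling_time),
    detectability = as.numeric(detectability)
  )
}

#' Describe a patch type
#'
#' @param patch_type_id Small positive integer identifying the patch type.
#' @param abundances Named numeric vector mapping resource id to abundance
#'   `A` (maximum encounterable items per time step per individual); names
#'   are resource ids.
#' @return A list of class `patch_type_spec`.
#' @examples
#' patch_type_spec(1, c(`1` = 1, `2` = 5))
#' @export
patch_type_spec <- function(patch_type_id, abundances) {
  if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
    rlang::abort("`abundances` must be a named vector (names = resource ids)",
                 class = "dispersyn_config_error")
  }
  structure(
    list(patch_type_id = as.integer(patch_type_id),
         abundances = vapply(abundances, as.numeric, numeric(1))),
    class = "patch_type_spec"
  )
}

#' Build a simulation configuration
#'
#' Collects the full parameterisation of one run: the world (patches,
#' carrying capacity, generations), the seasonal schedule (`t_before` time
#' steps of foraging, a single instantaneous dispersal event, `t_after`
#' further steps), the lifecycle coefficients (dispersal mortality `M`,
#' learning cost `alpha`, competition factor `Phi`), the mutation scheme,
#' the patch-extinction regime, and the resource/patch-type composition of
#' the environment.
#'
#' @param n_patches,n_individuals,n_generations World dimensions:
#'   number of patches, per-patch carrying capacity, generations to run.
#' @param t_before,t_after Lengths (time steps) of the pre- and
#'   post-dispersal foraging phases; the season length is their sum.
#' @param dispersal_mortality Probability `M` in `[0, 1]` that a dispersal
#'   attempt is fatal.
#' @param learning_cost Cost coefficient `alpha >= 0` in the fecundity
#'   equation `F = V_total * (1 - L * alpha)`.
#' @param mutation_prob,mutation_sd Per-locus mutation probability `mu` and
#'   the SD of the Gaussian perturbation (clamped to `[0, 1]`).
#' @param competition_factor Positive `Phi` scaling the per-patch resource
#'   cap downward.
#' @param extinction_every Period (generations) of the patch-extinction
#'   events, or `NULL` for no extinctions.
#' @param extinction_count Number of patches erased per event.
#' @param resources Tibble of resource types, usually built by stacking
#'   [resource_spec()] rows.
#' @param patch_types List of [patch_type_spec()] objects.
#' @param patch_type_assignment Integer vector of length `n_patches` giving
#'   each patch's type; defaults to the first half of patches taking the
#'   first type and the second half the second (dispersal is global, so the
#'   spatial arrangement is immaterial).
#' @param seed Optional non-negative integer default seed for the run.
#' @return A list of class `sim_config` (validated; see [validate_config()]).
#' @examples
#' cfg <- season_preset(10)
#' cfg$n_patches
#' @export
sim_config <- function(n_patches, n_individuals, n_generations,
                       t_before, t_after,
                       dispersal_mortality = 0.01,
                       learning_cost = 1.4,
                       mutation_prob = 0.1,
                       mutation_sd = 0.1,
                       competition_factor = 2,
                       extinction_every = 2,
                       extinction_count = 1,
                       resources,
                       patch_types,
                       patch_type_assignment = NULL,
                       seed = NULL) {
  cfg <- structure(
    list(
      n_patches = n_patches, n_individuals = n_individuals,
      n_generations = n_generations,
      t_before = t_before, t_after = t_after,
      dispersal_mortality = dispersal_mortality,
      learning_cost = learning_cost,
      mutation_prob = mutation_prob, mutation_sd = mutation_sd,
      competition_factor = competition_factor,
      extinction_every = extinction_every,
      extinction_count = extinction_count,
      resources = resources, patch_types = patch_types,
      patch_type_assignment = patch_type_assignment,
      seed = seed
    ),
    class = "sim_config"
  )
  validate_config(cfg)
}

cfg_err <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "dispersyn_config_error")
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integerish = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    cfg_err("missing field: `%s`", name)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    cfg_err("field `%s` must be a single number", name)
  }
  if (x < lo || x > hi) {
    cfg_err("field `%s` = %g out of range [%g, %g]", name, x, lo, hi)
  }
  if (integerish && x != floor(x)) {
    cfg_err("field `%s` = %g must be an integer", name, x)
  }
  invisible(NULL)
}

#' Validate and normalise a simulation configuration
#'
#' Checks every structural invariant of the configuration (field presence,
#' ranges, unique resource ids, at most ten resource types, resource ids
#' referenced by patch types all defined, assignment length, extinction
#' count not exceeding the number of patches, season length at least 2) and
#' returns the normalised configuration with integer fields coerced, the
#' default patch-type assignment filled in, and a default seed of 0 if none
#' was given. Each violation raises a classed error
#' (`dispersyn_config_error`) naming the offending field.
#'
#' @param cfg A `sim_config` or a bare list with the same fields.
#' @return The normalised `sim_config`.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) cfg_err("configuration must be a list")
  check_scalar(cfg$n_patches, "n_patches", lo = 1, integerish = TRUE)
  check_scalar(cfg$n_individuals, "n_individuals", lo = 1, integerish = TRUE)
  check_scalar(cfg$n_generations, "n_generations", lo = 0, integerish = TRUE)
  check_scalar(cfg$t_before, "t_before", lo = 1, integerish = TRUE)
  check_scalar(cfg$t_after, "t_after", lo = 1, integerish = TRUE)
  if (cfg$t_before + cfg$t_after < 2) cfg_err("season length must be >= 2")
  check_scalar(cfg$dispersal_mortality, "dispersal_mortality", 0, 1)
  check_scalar(cfg$learning_cost, "learning_cost", lo = 0)
  check_scalar(cfg$mutation_prob, "mutation_prob", 0, 1)
  check_scalar(cfg$mutation_sd, "mutation_sd", lo = 0)
  check_scalar(cfg$competition_factor, "competition_factor", lo = .Machine$double.eps)
  check_scalar(cfg$extinction_every, "extinction_every", lo = 1,
               integerish = TRUE, allow_null = TRUE)
  check_scalar(cfg$extinction_count, "extinction_count", lo = 0, integerish = TRUE)
  if (cfg$extinction_count > cfg$n_patches) {
    cfg_err("extinction_count (%d) exceeds n_patches (%d)",
            cfg$extinction_count, cfg$n_patches)
  }

  res <- cfg$resources
  if (is.null(res) || nrow(res) == 0) cfg_err("missing field: `resources`")
  res <- tibble::as_tibble(res)
  needed <- c("resource_id", "value", "handling_time", "detectability")
  miss <- setdiff(needed, names(res))
  if (length(miss)) cfg_err("resources missing column(s): %s", toString(miss))
  if (anyDuplicated(res$resource_id)) cfg_err("duplicate resource_id in resources")
  if (nrow(res) > 10) cfg_err("at most 10 resource types are supported")
  if (any(res$resource_id < 1 | res$resource_id > 10)) {
    cfg_err("resource_id must lie in 1..10")
  }
  if (any(res$value < 0)) cfg_err("resource `value` must be non-negative")
  if (any(res$handling_time < 1)) cfg_err("`handling_time` must be >= 1")
  if (any(res$detectability < 0 | res$detectability > 1)) {
    cfg_err("`detectability` must lie in [0, 1]")
  }
  res$resource_id <- as.integer(res$resource_id)
  cfg$resources <- res

  if (is.null(cfg$patch_types) || !length(cfg$patch_types)) {
    cfg_err("missing field: `patch_types`")
  }
  pt_ids <- vapply(cfg$patch_types, function(p) p$patch_type_id, integer(1))
  if (anyDuplicated(pt_ids)) cfg_err("duplicate patch_type_id")
  for (p in cfg$patch_types) {
    rid <- as.integer(names(p$abundances))
    unknown <- setdiff(rid, res$resource_id)
    if (length(unknown)) {
      cfg_err("patch type %d references unknown resource_id %s",
              p$patch_type_id, toString(unknown))
    }
    if (any(p$abundances < 0)) cfg_err("abundances must be non-negative")
  }

  if (is.null(cfg$patch_type_assignment)) {
    cfg$patch_type_assignment <-
      pt_ids[ceiling(seq_len(cfg$n_patches) / (cfg$n_patches / length(pt_ids)))]
  }
  asg <- as.integer(cfg$patch_type_assignment)
  if (length(asg) != cfg$n_patches) {
    cfg_err("patch_type_assignment length %d != n_patches %d",
            length(asg), cfg$n_patches)
  }
  if (!all(asg %in% pt_ids)) cfg_err("patch_type_assignment uses unknown patch_type_id")
  cfg$patch_type_assignment <- asg

  if (is.null(cfg$seed)) cfg$seed <- 0L
  check_scalar(cfg$seed, "seed", lo = 0, integerish = TRUE)

  for (f in c("n_patches", "n_individuals", "n_generations", "t_before",
              "t_after", "extinction_count", "seed")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (!is.null(cfg$extinction_every)) {
    cfg$extinction_every <- as.integer(cfg$extinction_every)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d patches x %d individuals, %d generations\n",
    x$n_patches, x$n_individuals, x$n_generations))
  cat(sprintf("  season: t_before = %d, t_after = %d (S = %d)\n",
              x$t_before, x$t_after, x$t_before + x$t_after))
  cat(sprintf("  M = %g, alpha = %g, Phi = %g, mu = %g (sd %g)\n",
              x$dispersal_mortality, x$learning_cost, x$competition_factor,
              x$mutation_prob, x$mutation_sd))
  cat(sprintf("  extinction: %s, %d patch(es)\n",
              if (is.null(x$extinction_every)) "never"
              else sprintf("every %d generations", x$extinction_every),
              x$extinction_count))
  cat(sprintf("  %d resource type(s), %d patch type(s)\n",
              nrow(x$resources), length(x$patch_types)))
  invisible(x)
}

# abundance matrix [patch_type rows in pt id order] x [resource in cfg order]
abundance_matrix <- function(cfg) {
  pt_ids <- vapply(cfg$patch_types, function(p) p$patch_type_id, integer(1))
  A <- matrix(0, nrow = max(pt_ids), ncol = nrow(cfg$resources),
              dimnames = list(NULL, cfg$resources$resource_id))
  for (p in cfg$patch_types) {
    A[p$patch_type_id, as.character(names(p$abundances))] <- p$abundances
  }
  A
}

#' Season-length experiment preset
#'
#' The reference environment for the season-length experiment: 12 patches of
#' two equally frequent types, carrying capacity 100, an easy resource
#' (id 1: `V = 1`, `H = 1`, `C = 0.5`, `A = 1`) present everywhere, and one
#' hard-to-access resource per patch type (ids 2 and 3: `V = 10`, `H = 300`,
#' `C = 0.5`, `A = 5`), with `M = 0.01`, `alpha = 1.4`, `mu = 0.1`
#' (SD 0.1), `Phi = 2`, and one random patch erased every second
#' generation. Both foraging phases last `t_phase` steps, so the season
#' length is `2 * t_phase`.
#'
#' @param t_phase Length of each foraging phase (time steps).
#' @param n_generations Generations to run (default 300).
#' @param ... Overrides passed on to [sim_config()].
#' @return A validated `sim_config`.
#' @export
season_preset <- function(t_phase, n_generations = 300, ...) {
  defaults <- list(
    n_patches = 12, n_individuals = 100, n_generations = n_generations,
    t_before = t_phase, t_after = t_phase,
    dispersal_mortality = 0.01, learning_cost = 1.4,
    mutation_prob = 0.1, mutation_sd = 0.1,
    competition_factor = 2, extinction_every = 2, extinction_count = 1,
    resources = dplyr::bind_rows(
      resource_spec(1, value = 1, handling_time = 1, detectability = 0.5),
      resource_spec(2, value = 10, handling_time = 300, detectability = 0.5),
      resource_spec(3, value = 10, handling_time = 300, detectability = 0.5)
    ),
    patch_types = list(
      patch_type_spec(1, c(`1` = 1, `2` = 5)),
      patch_type_spec(2, c(`1` = 1, `3` = 5))
    )
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

#' Dispersal-timing experiment preset
#'
#' The reference environment for the dispersal-timing experiment: as
#' [season_preset()] but with the hard resources at `H = 150`,
#' `Phi = 6`, 500 generations, and a fixed total season length of 20 split
#' into `t_before` pre-dispersal and `20 - t_before` post-dispersal steps.
#'
#' @param t_before Pre-dispersal phase length; `t_after` is `20 - t_before`.
#' @param n_generations Generations to run (default 500).
#' @param ... Overrides passed on to [sim_config()].
#' @return A validated `sim_config`.
#' @export
timing_preset <- function(t_before, n_generations = 500, ...) {
  stopifnot(t_before >= 1, t_before <= 19)
  defaults <- list(
    n_patches = 12, n_individuals = 100, n_generations = n_generations,
    t_before = t_before, t_after = 20L - as.integer(t_before),
    dispersal_mortality = 0.01, learning_cost = 1.4,
    mutation_prob = 0.1, mutation_sd = 0.1,
    competition_factor = 6, extinction_every = 2, extinction_count = 1,
    resources = dplyr::bind_rows(
      resource_spec(1, value = 1, handling_time = 1, detectability = 0.5),
      resource_spec(2, value = 10, handling_time = 150, detectability = 0.5),
      resource_spec(3, value = 10, handling_time = 150, detectability = 0.5)
    ),
    patch_types = list(
      patch_type_spec(1, c(`1` = 1, `2` = 5)),
      patch_type_spec(2, c(`1` = 1, `3` = 5))
    )
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the [sim_config()] fields, grouped into `world`,
#' `lifecycle`, `mutation` and `extinction` sections plus `resources` and
#' `patch_types` lists; see the presets under
#' `system.file("extdata", "presets", package = "dispersyn")` for the
#' layout.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    cfg_err("config file not found: %s", path)
  }
  y <- yaml::read_yaml(path)
  resources <- dplyr::bind_rows(lapply(y$resources, function(r) {
    resource_spec(r$resource_id, r$value, r$handling_time, r$detectability)
  }))
  patch_types <- lapply(y$patch_types, function(p) {
    patch_type_spec(p$patch_type_id, unlist(p$abundances))
  })
  w <- y$world; l <- y$lifecycle; m <- y$mutation; e <- y$extinction
  validate_config(structure(list(
    n_patches = w$n_patches, n_individuals = w$n_individuals,
    n_generations = w$n_generations,
    t_before = l$t_before, t_after = l$t_after,
    dispersal_mortality = l$dispersal_mortality,
    learning_cost = l$learning_cost,
    competition_factor = l$competition_factor,
    mutation_prob = m$mutation_prob, mutation_sd = m$mutation_sd,
    extinction_every = e$extinction_every,
    extinction_count = e$extinction_count,
    resources = resources, patch_types = patch_types,
    patch_type_assignment = y$patch_type_assignment,
    seed = y$seed
  ), class = "sim_config"))
}

#' Write a simulation configuration to a YAML file
#'
#' @param cfg A validated `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  y <- list(
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
    resources = lapply(seq_len(nrow(cfg$resources)), function(i) {
      as.list(cfg$resources[i, ])
    }),
    patch_types = lapply(cfg$patch_types, function(p) {
      list(patch_type_id = p$patch_type_id,
           abundances = as.list(p$abundances))
    }),
    patch_type_assignment = cfg$patch_type_assignment,
    seed = cfg$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
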