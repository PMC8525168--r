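# Internal population layout: a list of parallel columns so that whole-
# population operations stay vectorised.
#   loci      n x 5 matrix, columns d, l_r, l_d, e_r, e_d, all in [0,1]
#   disperser logical (NA until the developmental switch has fired)
#   L, E      expressed learning ability / exploration tendency
#   natal     natal patch index (never changes)
#   patch     current patch index
#   vtot      accumulated resource value V_total
#   exper     n x n_resources matrix of cumulative handled-item counts,
#             columns in the order of cfg$resources
LOCI <- c("d", "l_r", "l_d", "e_r", "e_d")

new_population <- function(loci, natal, n_resources) {
  n <- nrow(loci)
  list(
    loci = loci,
    disperser = rep(NA, n),
    L = rep(NA_real_, n),
    E = rep(NA_real_, n),
    natal = as.integer(natal),
    patch = as.integer(natal),
    vtot = numeric(n),
    exper = matrix(0L, nrow = n, ncol = n_resources)
  )
}

pop_size <- function(pop) length(pop$patch)

pop_subset <- function(pop, keep) {
  list(loci = pop$loci[keep, , drop = FALSE],
       disperser = pop$disperser[keep],
       L = pop$L[keep], E = pop$E[keep],
       natal = pop$natal[keep], patch = pop$patch[keep],
       vtot = pop$vtot[keep],
       exper = pop$exper[keep, , drop = FALSE])
}

#' Initialise a founder world
#'
#' Fills every patch with exactly `n_individuals` founders whose five loci
#' (dispersal tendency and the phenotype-specific learning and exploration
#' loci) are drawn independently and uniformly from `[0, 1]`. Founders pass
#' the developmental switch immediately ([develop()]), start with empty
#' experience ledgers and zero accumulated resource value. Uses R's global
#' RNG stream; seed it (or run via [run_simulation()]) for reproducibility.
#'
#' @param cfg A validated `sim_config`.
#' @return A `world` list with elements `pop` (the population) and
#'   `extinct_patches` (initially none).
#' @export
init_world <- function(cfg) {
  cfg <- validate_config(cfg)
  n <- cfg$n_patches * cfg$n_individuals
  loci <- matrix(runif(n * 5L), nrow = n, ncol = 5L,
                 dimnames = list(NULL, LOCI))
  natal <- rep(seq_len(cfg$n_patches), each = cfg$n_individuals)
  pop <- new_population(loci, natal, nrow(cfg$resources))
  pop <- develop_population(pop)
  list(pop = pop)
}

#' View a world's population as a tibble
#'
#' One row per living individual: the five loci, the developmental outcome
#' and expressed traits, patch bookkeeping, accumulated resource value and
#' the per-resource experience counts (`exp_<resource_id>` columns).
#'
#' @param world A world as returned by [init_world()] or advanced by
#'   [run_generation()].
#' @param cfg The configuration the world was built from (used for resource
#'   ids in column names).
#' @return A tibble.
#' @export
world_tibble <- function(world, cfg) {
  pop <- world$pop
  out <- tibble::as_tibble(as.data.frame(pop$loci))
  out$is_disperser <- pop$disperser
  out$expressed_l <- pop$L
  out$expressed_e <- pop$E
  out$natal_patch <- pop$natal
  out$current_patch <- pop$patch
  out$v_total <- pop$vtot
  ex <- as.data.frame(pop$exper)
  names(ex) <- paste0("exp_", cfg$resources$resource_id)
  dplyr::bind_cols(out, tibble::as_tibble(ex))
}
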