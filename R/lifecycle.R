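# Developmental switch, dispersal with mortality, fecundity, fitness-
# proportional recruitment, mutation, and periodic patch extinction.

#' Developmental switch
#'
#' At the very beginning of life each individual compares its dispersal
#' tendency `D` against a fresh uniform draw: if `D > u` it is destined to
#' disperse and irreversibly expresses its disperser loci (`l_d`, `e_d`),
#' otherwise its resident loci (`l_r`, `e_r`). The outcome and the
#' expressed traits never change afterwards.
#'
#' @param genotypes A data frame (or tibble) with columns `d`, `l_r`,
#'   `l_d`, `e_r`, `e_d`, one row per individual.
#' @return A tibble with columns `is_disperser`, `expressed_l`,
#'   `expressed_e`, rows aligned with the input. Uses R's global RNG.
#' @examples
#' set.seed(1)
#' develop(data.frame(d = c(0, 1), l_r = 0.2, l_d = 0.8, e_r = 0.5, e_d = 0.5))
#' @export
develop <- function(genotypes) {
  n <- nrow(genotypes)
  u <- runif(n)
  disp <- genotypes$d > u
  tibble::tibble(
    is_disperser = disp,
    expressed_l = ifelse(disp, genotypes$l_d, genotypes$l_r),
    expressed_e = ifelse(disp, genotypes$e_d, genotypes$e_r)
  )
}

# in-place, matrix-based variant used by the engine
develop_population <- function(pop) {
  n <- pop_size(pop)
  u <- runif(n)
  disp <- pop$loci[, "d"] > u
  pop$disperser <- disp
  pop$L <- ifelse(disp, pop$loci[, "l_d"], pop$loci[, "l_r"])
  pop$E <- ifelse(disp, pop$loci[, "e_d"], pop$loci[, "e_r"])
  pop
}

#' Dispersal phase
#'
#' Between the two foraging phases every disperser either dies (probability
#' `M`: a uniform draw below the mortality risk removes it entirely, with
#' no post-phase foraging and no reproduction) or relocates to a patch
#' drawn uniformly from all patches, the natal patch included. Residents
#' are untouched. Dispersal consumes no time.
#'
#' @param world World list.
#' @param cfg Validated `sim_config`.
#' @return A list with the updated `world` and `n_died`, the count of
#'   dispersal fatalities.
#' @export
dispersal_phase <- function(world, cfg) {
  pop <- world$pop
  n <- pop_size(pop)
  if (n == 0) return(list(world = world, n_died = 0L))
  disp <- which(pop$disperser)
  n_died <- 0L
  if (length(disp)) {
    dies <- runif(length(disp)) < cfg$dispersal_mortality
    n_died <- sum(dies)
    survivors <- disp[!dies]
    if (length(survivors)) {
      pop$patch[survivors] <- sample.int(cfg$n_patches, length(survivors),
                                         replace = TRUE)
    }
    if (n_died > 0) {
      keep <- rep(TRUE, n)
      keep[disp[dies]] <- FALSE
      pop <- pop_subset(pop, keep)
    }
  }
  world$pop <- pop
  list(world = world, n_died = n_died)
}

#' Fecundity
#'
#' `F = max(0, V_total * (1 - L * alpha))`: resource income discounted by
#' the multiplicative cost of the expressed learning ability. The floor at
#' zero keeps `F` usable as a sampling weight (with `alpha = 1.4` the raw
#' expression goes negative for `L > 1/1.4`).
#'
#' @param v_total Accumulated resource value.
#' @param expressed_l Expressed learning ability `L`.
#' @param learning_cost Cost coefficient `alpha`.
#' @return Non-negative fecundity; vectorised.
#' @examples
#' fecundity(100, 0.5, 1.4) # 30
#' fecundity(100, 1.0, 1.4) # 0 (floored)
#' @export
fecundity <- function(v_total, expressed_l, learning_cost) {
  pmax(0, v_total * (1 - expressed_l * learning_cost))
}

#' Recruit one patch's next generation
#'
#' Samples exactly `carrying_capacity` offspring genotypes with
#' replacement, each parent drawn with probability proportional to its
#' fecundity among the patch's occupants; offspring are exact copies of
#' the parental loci (mutation is applied separately). An empty patch
#' recruits nothing (it can only be recolonised by immigrants); an
#' occupied patch whose fecundities are all zero recruits uniformly.
#'
#' @param loci Matrix (occupants x 5) of parental loci.
#' @param f Numeric vector of occupant fecundities.
#' @param carrying_capacity Number of offspring to recruit.
#' @return Matrix (`carrying_capacity` x 5) of offspring loci, or a
#'   0-row matrix for an empty patch.
#' @export
recruit_patch <- function(loci, f, carrying_capacity) {
  n <- nrow(loci)
  if (n == 0) return(loci[0, , drop = FALSE])
  if (all(f == 0)) f <- rep(1, n)
  idx <- sample.int(n, carrying_capacity, replace = TRUE, prob = f)
  loci[idx, , drop = FALSE]
}

#' Mutate genotypes
#'
#' Each of the five loci independently mutates with probability `mu`; a
#' mutated locus is redrawn from a Gaussian centred on the parental value
#' with the given SD and clamped to `[0, 1]`.
#'
#' @param loci Matrix (individuals x 5) of loci.
#' @param mutation_prob Per-locus mutation probability `mu`.
#' @param mutation_sd SD of the Gaussian perturbation.
#' @return The mutated loci matrix.
#' @export
mutate_genotypes <- function(loci, mutation_prob, mutation_sd) {
  if (mutation_prob <= 0 || length(loci) == 0) return(loci)
  hit <- runif(length(loci)) < mutation_prob
  if (any(hit)) {
    loci[hit] <- pmin(1, pmax(0, rnorm(sum(hit), mean = loci[hit],
                                       sd = mutation_sd)))
  }
  loci
}

#' Periodic patch extinction
#'
#' Every `extinction_every` generations (i.e. when the generation index is
#' a multiple of the period), `extinction_count` distinct patches chosen
#' uniformly at random are emptied of all individuals; in other
#' generations the world passes through unchanged. Applied to the
#' offspring cohort at the end of a generation.
#'
#' @param world World list.
#' @param cfg Validated `sim_config`.
#' @param generation_index 1-based generation counter.
#' @return The updated world.
#' @export
apply_extinction <- function(world, cfg, generation_index) {
  if (is.null(cfg$extinction_every) || cfg$extinction_count == 0 ||
      generation_index %% cfg$extinction_every != 0) {
    return(world)
  }
  doomed <- sample.int(cfg$n_patches, cfg$extinction_count)
  keep <- !(world$pop$patch %in% doomed)
  world$pop <- pop_subset(world$pop, keep)
  world
}
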