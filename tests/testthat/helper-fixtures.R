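# Brute-force per-item loop: the independent oracle for the learning-
# discounted handling sum. Deliberately literal, never vectorised.
loop_handled <- function(n_items, handling_time, learning, prior = 0) {
  total <- 0
  if (n_items < 1) return(0)
  for (j in (prior + 1):(prior + n_items)) {
    term <- if (learning <= 0 && handling_time > 1) 0 else {
      1 - (handling_time - 1) / (j * learning)
    }
    if (handling_time <= 1) term <- 1
    total <- total + max(0, term)
  }
  total
}

# Small fast world: 2 patches x a handful of individuals, one easy and one
# hard resource, short seasons.
tiny_config <- function(...) {
  defaults <- list(
    n_patches = 2, n_individuals = 10, n_generations = 10,
    t_before = 5, t_after = 5,
    dispersal_mortality = 0.01, learning_cost = 1.4,
    mutation_prob = 0.1, mutation_sd = 0.1,
    competition_factor = 2, extinction_every = 2, extinction_count = 1,
    resources = dplyr::bind_rows(
      resource_spec(1, value = 1, handling_time = 1, detectability = 0.5),
      resource_spec(2, value = 10, handling_time = 20, detectability = 0.5)
    ),
    patch_types = list(
      patch_type_spec(1, c(`1` = 1, `2` = 5)),
      patch_type_spec(2, c(`1` = 1))
    )
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

# A one-patch world holding hand-built individuals (all residents unless
# stated), for targeted foraging checks.
manual_world <- function(cfg, L, E, patch = 1) {
  n <- length(L)
  loci <- matrix(0, nrow = n, ncol = 5, dimnames = list(NULL, dispersyn:::LOCI))
  loci[, "l_r"] <- L
  loci[, "e_r"] <- E
  pop <- dispersyn:::new_population(loci, rep(patch, n), nrow(cfg$resources))
  pop$disperser <- rep(FALSE, n)
  pop$L <- L
  pop$E <- E
  list(pop = pop)
}
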