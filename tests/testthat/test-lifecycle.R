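test_that("the developmental switch fires with probability D and is irreversible", {
  g <- data.frame(d = c(0, 1), l_r = 0.2, l_d = 0.9, e_r = 0.1, e_d = 0.8)
  set.seed(2)
  out <- develop(g)
  expect_false(out$is_disperser[1])  # D = 0 can never exceed the draw
  expect_true(out$is_disperser[2])   # D = 1 always does
  expect_equal(out$expressed_l, c(0.2, 0.9))
  expect_equal(out$expressed_e, c(0.1, 0.8))

  set.seed(13)
  n <- 1e5
  frac <- mean(develop(data.frame(d = rep(0.5, n), l_r = 0, l_d = 0,
                                  e_r = 0, e_d = 0))$is_disperser)
  expect_equal(frac, 0.5, tolerance = 0.02)
})

test_that("dispersal kills with probability M and relocates uniformly", {
  cfg <- tiny_config()
  set.seed(17)
  w <- init_world(cfg)

  cfg_m0 <- tiny_config(dispersal_mortality = 0)
  r0 <- dispersal_phase(w, cfg_m0)
  expect_equal(r0$n_died, 0L)
  expect_equal(dispersyn:::pop_size(r0$world$pop), dispersyn:::pop_size(w$pop))

  cfg_m1 <- tiny_config(dispersal_mortality = 1)
  r1 <- dispersal_phase(w, cfg_m1)
  expect_equal(r1$n_died, sum(w$pop$disperser))
  expect_false(any(r1$world$pop$disperser))

  # survivors keep phenotype and natal patch; residents never move
  surv <- r0$world$pop
  expect_equal(surv$L, w$pop$L)
  expect_equal(surv$natal, w$pop$natal)
  res <- !w$pop$disperser
  expect_equal(surv$patch[res], w$pop$patch[res])

  # destination uniformity over 12 patches
  cfg12 <- season_preset(2, n_generations = 1, dispersal_mortality = 0)
  n <- 1e5
  loci <- matrix(1, nrow = n, ncol = 5,
                 dimnames = list(NULL, dispersyn:::LOCI))
  pop <- dispersyn:::new_population(loci, rep(1L, n), 3)
  pop$disperser <- rep(TRUE, n); pop$L <- rep(1, n); pop$E <- rep(1, n)
  set.seed(19)
  moved <- dispersal_phase(list(pop = pop), cfg12)$world$pop
  counts <- tabulate(moved$patch, 12)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.01)
})

test_that("fecundity is the income-times-cost product floored at zero", {
  expect_equal(fecundity(100, 0.5, 1.4), 30)
  expect_equal(fecundity(100, 0, 1.4), 100)
  expect_equal(fecundity(100, 1, 1.4), 0)   # floored from -40
  expect_true(all(fecundity(runif(100, 0, 50), runif(100), 1.4) >= 0))
})

test_that("recruitment is fitness-proportional with stated edge cases", {
  loci <- matrix(c(0.1, 0.9), nrow = 2, ncol = 5,
                 dimnames = list(NULL, dispersyn:::LOCI))
  set.seed(29)
  kids <- recruit_patch(loci, f = c(2, 1), carrying_capacity = 3e4)
  expect_equal(nrow(kids), 3e4)
  share1 <- mean(kids[, "d"] == 0.1)
  expect_equal(share1, 2 / 3, tolerance = 0.01)

  solo <- recruit_patch(loci[1, , drop = FALSE], f = 5, carrying_capacity = 7)
  expect_true(all(solo == loci[rep(1, 7), ]))

  empty <- recruit_patch(loci[0, , drop = FALSE], f = numeric(0),
                         carrying_capacity = 10)
  expect_equal(nrow(empty), 0L)

  # all-zero fitness in an occupied patch falls back to uniform sampling
  set.seed(31)
  kids0 <- recruit_patch(loci, f = c(0, 0), carrying_capacity = 2e4)
  expect_equal(mean(kids0[, "d"] == 0.1), 0.5, tolerance = 0.02)
})

test_that("mutation perturbs loci independently and clamps to [0, 1]", {
  loci <- matrix(runif(500), nrow = 100, ncol = 5,
                 dimnames = list(NULL, dispersyn:::LOCI))
  expect_identical(mutate_genotypes(loci, 0, 0.1), loci)
  expect_equal(mutate_genotypes(loci, 1, 0), loci)

  set.seed(37)
  zero <- matrix(0, nrow = 2e4, ncol = 5,
                 dimnames = list(NULL, dispersyn:::LOCI))
  mut <- mutate_genotypes(zero, 1, 0.1)
  expect_true(all(mut >= 0 & mut <= 1))
  # clamped half-normal: about half the draws pin at exactly 0
  expect_equal(mean(mut == 0), 0.5, tolerance = 0.01)

  set.seed(41)
  big <- matrix(runif(1e5), nrow = 2e4, ncol = 5,
                dimnames = list(NULL, dispersyn:::LOCI))
  some <- mutate_genotypes(big, 0.1, 0.1)
  expect_equal(mean(some != big), 0.1, tolerance = 0.05)
})

test_that("patch extinction erases whole patches on schedule", {
  cfg <- tiny_config()
  set.seed(43)
  w <- init_world(cfg)
  expect_identical(apply_extinction(w, cfg, generation_index = 3), w)

  cfg0 <- tiny_config(extinction_count = 0)
  expect_identical(apply_extinction(w, cfg0, 2), w)

  set.seed(47)
  hit <- apply_extinction(w, cfg, generation_index = 2)
  occ <- tabulate(hit$pop$patch, cfg$n_patches)
  expect_equal(sum(occ == 0), 1L)
  expect_equal(sum(occ), dispersyn:::pop_size(w$pop) - cfg$n_individuals)

  cfg_all <- tiny_config(extinction_count = 2)
  set.seed(53)
  gone <- apply_extinction(w, cfg_all, 2)
  expect_equal(dispersyn:::pop_size(gone$pop), 0L)
})
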