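test_that("encounter and detection follow the stated closed forms", {
  expect_equal(max_encounters(5, 25, 1), 250)
  expect_equal(max_encounters(5, 25, 0), 125)   # exactly half the E=1 yield
  expect_equal(max_encounters(0, 17, 0.3), 0)

  expect_equal(detected_items(250, 0.5, 1), 125)
  expect_equal(detected_items(250, 0.5, 0), 250)
  expect_equal(detected_items(250, 1.0, 0.7), 250)

  # detection never exceeds encounters; both monotone as stated
  set.seed(5)
  A <- runif(200, 0, 10); Tt <- sample(1:100, 200, TRUE)
  E <- runif(200); C <- runif(200)
  n <- max_encounters(A, Tt, E)
  expect_true(all(detected_items(n, C, E) <= n + 1e-12))
})

test_that("handled_sum reproduces the per-item loop oracle", {
  expect_equal(handled_sum(125, 1, 0, 0)$handled, 125)
  expect_equal(handled_sum(125, 300, 1, 0)$handled, 0)
  # frozen value computed with the literal loop oracle
  expect_equal(handled_sum(500, 300, 1, 0)$handled, 47.4656279757,
               tolerance = 1e-9)
  expect_equal(handled_sum(500, 300, 1, 0)$handled,
               loop_handled(500, 300, 1, 0), tolerance = 1e-10)

  set.seed(23)
  for (i in 1:1000) {
    n <- sample(0:600, 1)
    H <- sample(c(1, 2, 20, 150, 300), 1)
    L <- runif(1)
    prior <- sample(0:500, 1)
    got <- handled_sum(n, H, L, prior)
    expect_equal(got$handled, loop_handled(n, H, L, prior),
                 tolerance = 1e-9,
                 info = sprintf("n=%d H=%g L=%g prior=%d", n, H, L, prior))
    expect_equal(got$new_experience, prior + n)
  }
})

test_that("handled_sum is monotone in learning and in prior experience", {
  set.seed(31)
  n <- sample(50:400, 50, TRUE)
  H <- sample(c(20, 150, 300), 50, TRUE)
  L <- runif(50)
  prior <- sample(0:400, 50, TRUE)
  base <- handled_sum(n, H, L, prior)$handled
  more_L <- handled_sum(n, H, pmin(1, L + 0.1), prior)$handled
  more_prior <- handled_sum(n, H, L, prior + 100)$handled
  expect_true(all(more_L >= base - 1e-12))
  expect_true(all(more_prior >= base - 1e-12))
  # experience carry-over strictly helps once terms are in range
  expect_gt(handled_sum(100, 300, 1, 400)$handled,
            handled_sum(100, 300, 1, 0)$handled)
})

test_that("the patch cap and competition scaling behave as specified", {
  expect_equal(patch_resource_cap(25, 5, 100, 2), 6250)
  expect_equal(patch_resource_cap(25, 5, 100, 1), 25 * 5 * 100)
  expect_equal(patch_resource_cap(2, 5, 100, 6), 1000 / 6)

  h <- c(30, 50, 20)  # sums to 10 x cap -> everyone scaled by 0.1
  out <- apply_competition(h, cap = 10)
  expect_equal(out, h * 0.1)
  expect_equal(sum(out), 10)
  expect_equal(apply_competition(c(2, 3), cap = 10), c(2, 3))
  expect_equal(apply_competition(c(0, 0), cap = 10), c(0, 0))
})

test_that("forage_phase composes the pipeline over a patch", {
  # single occupant, easy resource only: N=25, N'=25, handled=25, no cap hit
  cfg <- sim_config(
    n_patches = 1, n_individuals = 100, n_generations = 1,
    t_before = 25, t_after = 25, competition_factor = 2,
    resources = resource_spec(1, value = 1, handling_time = 1,
                              detectability = 0.5),
    patch_types = list(patch_type_spec(1, c(`1` = 1))),
    patch_type_assignment = 1, extinction_every = NULL)
  w <- manual_world(cfg, L = 0, E = 0)
  w <- forage_phase(w, cfg, "before")
  expect_equal(w$pop$vtot, 25)
  expect_equal(w$pop$exper[1, 1], 25)

  # two identical occupants, handled 10 each, cap 10 -> 5 each
  cfg2 <- sim_config(
    n_patches = 1, n_individuals = 1, n_generations = 1,
    t_before = 10, t_after = 10, competition_factor = 1,
    resources = resource_spec(1, value = 1, handling_time = 1,
                              detectability = 0.5),
    patch_types = list(patch_type_spec(1, c(`1` = 1))),
    patch_type_assignment = 1, extinction_every = NULL)
  w2 <- manual_world(cfg2, L = c(0, 0), E = c(0, 0))
  w2 <- forage_phase(w2, cfg2, "before")  # cap = 10*1*1/1 = 10, each took 10
  expect_equal(w2$pop$vtot, c(5, 5))

  # experience carries across phases: ledger continues after phase 1
  cfg3 <- tiny_config(n_individuals = 1)
  w3 <- manual_world(cfg3, L = 1, E = 0)
  w3 <- forage_phase(w3, cfg3, "before")
  e1 <- w3$pop$exper[1, 2]
  w3b <- forage_phase(w3, cfg3, "after")
  expect_equal(w3b$pop$exper[1, 2], e1 + e1)  # same phase length, same intake
  expect_true(all(w3b$pop$exper[1, ] >= w3$pop$exper[1, ]))
})

test_that("per-patch post-competition totals never exceed the cap", {
  cfg <- tiny_config(n_individuals = 30, t_before = 8, t_after = 8)
  set.seed(99)
  w <- init_world(cfg)
  for (phase in c("before", "after")) {
    w <- forage_phase(w, cfg, phase, diagnostics = TRUE)
    d <- w$diagnostics
    expect_true(all(d$post_total <= d$cap + 1e-9))
    expect_true(all(d$post_total <= d$pre_total + 1e-12))
    binding <- d$pre_total > d$cap
    expect_equal(d$post_total[binding], d$cap[binding], tolerance = 1e-9)
  }
})
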