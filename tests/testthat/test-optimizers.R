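test_that("Levy flight steps are reproducible and heavy-tailed", {
  set.seed(1)
  expect_equal(levy_flight(5, scale = 0), rep(0, 5))
  a <- withr::with_seed(3, levy_flight(10))
  b <- withr::with_seed(3, levy_flight(10))
  expect_identical(a, b)

  steps <- withr::with_seed(11, levy_flight(1e5, beta = 1.5, scale = 1))
  expect_gt(sample_kurtosis(steps), 10 * 3)  # vastly heavier than any normal
})

test_that("GJO moves match hand arithmetic in both phases", {
  # exploration, 1-dim: YM = 2, Prey = 1, RL = 0.5, E = 2
  mv <- gjo_move(ym = 2, yfm = 3, prey = 1, E = 2, rl = 0.5, exploring = TRUE)
  expect_equal(mv$y1, 2 - 2 * abs(2 - 0.5 * 1))  # = -1
  expect_equal(mv$y1, -1)
  expect_equal(mv$y2, 3 - 2 * abs(3 - 0.5))

  # exploitation at E = 0 collapses onto the leaders' midpoint
  mv0 <- gjo_move(ym = 4, yfm = 2, prey = -1, E = 0, rl = 0.7, exploring = FALSE)
  expect_equal(mv0$y1, 4)
  expect_equal(mv0$y2, 2)
  expect_equal(mv0$new, 3)
})

test_that("WARSO attack and defense moves match hand arithmetic", {
  expect_equal(warso_attack(p = 0, king = 2, commander = 1,
                            rho = 0.5, R = 0.5, w = 1), 0)
  expect_equal(warso_defense(p = 1, king = 3, p_rand = 0, commander = 2,
                             rho = 0.5, R = 1, w = 0.5), 1 + 3 + 0.5)
})

test_that("WARSO accepts only non-degrading moves and decays weights", {
  sp <- box_space(rep(-5, 3), rep(5, 3))
  # constant objective: every move is accepted (Fn >= Fp), ranks climb
  set.seed(6)
  pos <- t(replicate(4, init_position(sp)))
  st <- warso_state(pos, rep(1, 4), sp, epochs = 3)
  obj <- function(x) 1
  for (k in 1:3) st <- warso_step(st, obj)
  expect_equal(st$rank, rep(3L, 4))
  expect_equal(st$weight, rep(0, 4))  # rank == max_iter drives weights to 0

  # an objective that scores 1 only at the original positions: every proposal
  # lands elsewhere, degrades, and must be rejected (position, rank and
  # weight untouched) -- except the unconditional weak-soldier relocation
  set.seed(8)
  pos0 <- t(replicate(3, init_position(sp)))
  orig <- lapply(1:3, function(i) pos0[i, ])
  obj_reject <- function(x) {
    if (any(vapply(orig, function(o) isTRUE(all.equal(o, x)), logical(1)))) 1 else 0
  }
  st0 <- warso_state(pos0, rep(1, 3), sp, epochs = 5)
  st0 <- warso_step(st0, obj_reject)
  expect_equal(st0$rank, rep(0L, 3))
  expect_equal(st0$weight, rep(1, 3))
  kept <- setdiff(1:3, st0$relocated)
  for (i in kept) expect_equal(st0$positions[i, ], orig[[i]])
})

test_that("WARSO per-soldier fitness never decreases outside relocation", {
  sp <- box_space(rep(-5, 4), rep(5, 4))
  sphere <- function(x) -sum(x^2)
  set.seed(10)
  pos <- t(replicate(8, init_position(sp)))
  fit <- apply(pos, 1, sphere)
  st <- warso_state(pos, fit, sp, epochs = 30)
  for (k in 1:30) {
    before <- st$fitness
    st <- warso_step(st, sphere)
    keep <- setdiff(seq_along(before), st$relocated)
    expect_true(all(st$fitness[keep] >= before[keep]))
    expect_true(all(st$positions >= -5 & st$positions <= 5))
    expect_equal(st$king_fitness, max(st$fitness))
  }
})

test_that("GJO exercises both energy phases over a full run", {
  sp <- box_space(rep(-5, 5), rep(5, 5))
  sphere <- function(x) -sum(x^2)
  res <- optimize_mha(sphere, sp, "gjo", population = 10, epochs = 50, seed = 2)
  expect_gt(res$state$n_explore, 0)
  expect_gt(res$state$n_exploit, 0)
  # linear energy decay: the final iterations are exploitation-only
  expect_equal(res$state$t, 50L)
})

test_that("optimization trajectories are monotone, bounded and deterministic", {
  sp <- box_space(rep(-5, 5), rep(5, 5))
  sphere <- function(x) -sum(x^2)
  for (m in c("gjo", "warso")) {
    r1 <- optimize_mha(sphere, sp, m, population = 12, epochs = 20, seed = 5)
    r2 <- optimize_mha(sphere, sp, m, population = 12, epochs = 20, seed = 5)
    expect_identical(r1$best_position, r2$best_position)
    expect_identical(r1$trajectory, r2$trajectory)
    expect_length(r1$trajectory, 20)
    expect_false(is.unsorted(r1$trajectory))
    expect_equal(r1$best_fitness, max(r1$trajectory))
    expect_true(all(r1$best_position >= -5 & r1$best_position <= 5))
    expect_true(all(r1$state$positions >= -5 & r1$state$positions <= 5))
  }
})

test_that("a constant objective leaves the trajectory flat", {
  sp <- box_space(c(0, 0), c(1, 1))
  r <- optimize_mha(function(x) 0.5, sp, "gjo", population = 5, epochs = 10, seed = 1)
  expect_equal(r$trajectory, rep(0.5, 10))
  expect_equal(r$best_fitness, 0.5)
})

test_that("non-finite objective values are discarded with a warning", {
  sp <- box_space(c(-2, -2), c(2, 2))
  bad <- function(x) if (x[1] > 0) NaN else -sum(x^2)
  w <- capture_warnings(
    r <- optimize_mha(bad, sp, "gjo", population = 6, epochs = 5, seed = 3)
  )
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(r$best_fitness))
})
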