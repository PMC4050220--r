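test_that("inertia weight is a linear schedule between its endpoints", {
  cfg <- swarm_config(k = 2)
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(cfg$max_iterations, cfg), 0.4)
  expect_equal(inertia_weight(50, cfg), 0.65)
  w <- vapply(0:100, inertia_weight, numeric(1), cfg = cfg)
  expect_true(all(diff(w) < 0))
  expect_equal(var(diff(w)), 0)
})

test_that("velocity update reproduces hand arithmetic and respects the clamp", {
  # v_new = 0.5*1 + 2*0.5*2 + 2*0.5*(-1) = 1.5
  v <- update_velocity(velocity = 1, position = 0, pbest_position = 2,
                       gbest_position = -1, w = 0.5, c1 = 2, c2 = 2,
                       v_max = 4, r1 = 0.5, r2 = 0.5)
  expect_equal(v, 1.5)
  # stationary point: x = pbest = gbest, v = 0
  expect_equal(update_velocity(0, 3, 3, 3, w = 0.9, r1 = 0.7, r2 = 0.1), 0)
  # clamp
  set.seed(4)
  for (i in 1:50) {
    v <- update_velocity(runif(4, -4, 4), runif(4, 1, 5), runif(4, 1, 5),
                         runif(4, 1, 5), w = 0.9, v_max = 2)
    expect_true(all(abs(v) <= 2))
  }
})

test_that("position update reflects off the search-box walls", {
  # interior move
  expect_equal(update_position(c(3, 2, 2, 1), c(1.5, 0, 0, 0), m = 5),
               c(4.5, 2, 2, 1))
  # overshoot reflects instead of sticking to the bound
  x <- update_position(c(5, 2, 3, 2), c(2, 0, 1.5, 0), m = 5)
  expect_equal(x, c(3, 2, 1.5, 2))
  # zero velocity is the identity
  expect_equal(update_position(c(2, 4, 1, 3), rep(0, 4), m = 5),
               c(2, 4, 1, 3))
  # always in bounds under random moves
  set.seed(8)
  for (i in 1:100) {
    x <- update_position(runif(4, 1, c(5, 5, 3, 3)),
                         runif(4, -1, 1) * c(4, 4, 2, 2), m = 5)
    expect_true(all(x >= 1) && all(x[1:2] <= 5) && all(x[3:4] <= 3))
  }
})

test_that("decoding rounds half away from zero and repairs collisions", {
  dec <- decode_particle(c(1.2, 4.4, 2.0, 3.0), m = 5)
  expect_identical(format(dec$barcode), "SNPs(1,4) 2-3")
  # genotype slot 2.5 rounds up to 3
  dec <- decode_particle(c(1, 3, 2.5, 1.4), m = 5)
  expect_identical(dec$barcode$genotype_codes, c(3L, 1L))
  # collision: second slot redrawn among unused, coordinate overwritten
  set.seed(3)
  for (i in 1:50) {
    dec <- decode_particle(c(3.0, 3.2, 1, 1), m = 5)
    expect_false(anyDuplicated(dec$barcode$snp_indices) > 0)
    expect_true(3L %in% dec$barcode$snp_indices)
    other <- setdiff(dec$barcode$snp_indices, 3L)
    expect_true(other %in% c(1L, 2L, 4L, 5L))
    expect_equal(dec$position[2], other)
  }
})

test_that("initial population satisfies the particle invariants", {
  ds <- dichotomize_by_mean(generate_dataset(synthetic_spec(seed = 14)))
  cfg <- swarm_config(k = 2, seed = 14)
  set.seed(cfg$seed)
  st <- init_population(cfg, ds)
  expect_identical(dim(st$positions), c(50L, 4L))
  for (i in 1:50) {
    bc <- decode_particle(st$positions[i, ], m = 5)$barcode
    expect_length(unique(bc$snp_indices), 2)
    expect_true(all(bc$snp_indices %in% 1:5))
    expect_true(all(bc$genotype_codes %in% 1:3))
  }
  expect_true(all(abs(st$velocities) <= rep(c(4, 4, 2, 2), each = 50)))
  expect_equal(st$gbest_fitness, max(st$pbest_fitness))
  expect_error(init_population(swarm_config(k = 6), ds), "exceeds")
})

test_that("seeded runs are exactly reproducible", {
  ds <- dichotomize_by_mean(generate_dataset(synthetic_spec(seed = 31)))
  cfg <- swarm_config(k = 3, seed = 31)
  r1 <- run_pso(ds, cfg)
  r2 <- run_pso(ds, cfg)
  expect_identical(format(r1$barcode), format(r2$barcode))
  expect_identical(r1$trace, r2$trace)
})

test_that("gbest fitness is monotone and decoded barcodes stay valid", {
  ds <- dichotomize_by_mean(generate_dataset(synthetic_spec(seed = 6)))
  cfg <- swarm_config(k = 2, max_iterations = 40, seed = 6)
  set.seed(cfg$seed)
  st <- init_population(cfg, ds)
  prev <- st$gbest_fitness
  for (t in 1:40) {
    st <- pso_step(st, ds, cfg)
    expect_gte(st$gbest_fitness, prev)
    prev <- st$gbest_fitness
    for (i in c(1, 25, 50)) {
      bc <- decode_particle(st$positions[i, ], m = 5)$barcode
      expect_false(anyDuplicated(bc$snp_indices) > 0)
      expect_true(all(bc$genotype_codes %in% 1:3))
      expect_true(all(abs(st$velocities[i, ]) <= c(4, 4, 2, 2)))
    }
  }
  expect_equal(st$gbest_fitness, max(st$pbest_fitness))
})

test_that("a dataset with a perfect barcode yields that barcode at |HIGH|", {
  spec <- synthetic_spec(carrier_prob_high = 1, carrier_prob_low = 0,
                         seed = 12)
  ds <- dichotomize_by_mean(generate_dataset(spec))
  res <- run_pso(ds, swarm_config(k = 2, seed = 12))
  expect_identical(format(res$barcode), "SNPs(1,4) 3-3")
  expect_equal(res$fitness, group_sizes(ds)[["n_high"]])
})

test_that("PSO never beats, and usually matches, the exhaustive oracle", {
  hits <- 0
  for (s in 41:50) {
    ds <- dichotomize_by_mean(generate_dataset(synthetic_spec(seed = s)))
    best <- exhaustive_best(ds, 2)$difference[1]
    res <- run_pso(ds, swarm_config(k = 2, seed = s))
    expect_lte(res$fitness, best)
    hits <- hits + (res$fitness == best)
  }
  expect_gte(hits, 8)
})
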