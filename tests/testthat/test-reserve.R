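test_that("p = 0 selects nothing and p = 100 needs both sides of every split", {
  R <- rbind(a1 = c(A = 1, B = 0), a2 = c(A = 0, B = 1))
  land <- tiny_landscape(R)
  one_split <- split_system(c("A", "B"), rbind(c(0, 1)), 5)

  sol0 <- solve_reserve(land, one_split, 0)
  expect_equal(sol0$status, "optimal")
  expect_length(sol0$areas, 0)
  expect_equal(sol0$objective, 0)

  sol100 <- solve_reserve(land, one_split, 100)
  expect_setequal(sol100$areas, c("a1", "a2"))
  expect_equal(sol100$sd_pct, 100)
})

test_that("a single area holding all taxa is optimal on its own", {
  R <- rbind(a1 = c(A = 1, B = 1, C = 1), a2 = c(A = 1, B = 0, C = 0))
  land <- tiny_landscape(R, cost = c(3, 1))
  sys <- unit_trivial_system(c("A", "B", "C"))
  sol <- solve_reserve(land, sys, 100)
  expect_equal(sol$areas, "a1")
  expect_equal(sol$cost, 3)
})

test_that("infeasibility is reported structurally, with the uncoverable taxa named", {
  R <- rbind(a1 = c(A = 1, B = 0))
  land <- tiny_landscape(R)
  sys <- unit_trivial_system(c("A", "B"))
  sol <- solve_reserve(land, sys, 100)
  expect_equal(sol$status, "infeasible")
  expect_match(sol$diagnostics, "B")
})

test_that("reserve ILP equals the enumeration oracle on an 8-area grid fixture", {
  spec <- synth_spec(seed = 31, n_taxa = 7, grid_dim = 3)
  system <- aggregate_trees(gen_tree_collection(spec))
  land_full <- gen_landscape(spec, beta = 1)
  keep <- 1:8
  land <- landscape(land_full$R[keep, , drop = FALSE],
                    land_full$cost[keep], land_full$B[keep, keep],
                    beta = 1, urban = land_full$urban[keep])
  for (p in c(80, 95)) {
    bf <- brute_force_reserve(land, system, p)
    sol <- solve_reserve(land, system, p)
    expect_equal(sol$objective, bf$objective, tolerance = 1e-9)
    expect_gte(sol$sd_pct, p - 1e-6)
  }
})

test_that("optimal cost is non-decreasing in the diversity target p", {
  spec <- synth_spec(seed = 17, n_taxa = 6, grid_dim = 3)
  system <- aggregate_trees(gen_tree_collection(spec))
  land <- gen_landscape(spec, beta = 1)
  costs <- vapply(c(0, 25, 50, 75, 100), function(p) {
    solve_reserve(land, system, p)$objective
  }, numeric(1))
  expect_true(all(diff(costs) >= -1e-9))
})

test_that("co-selecting adjacent areas saves exactly twice the shared boundary", {
  spec <- synth_spec(seed = 2, n_taxa = 4, grid_dim = 2)
  land <- gen_landscape(spec, beta = 1)
  # areas 1 and 2 are horizontal neighbors on the 2x2 grid
  f_joint <- fence_length(land, c(1, 2))
  f_apart <- fence_length(land, 1) + fence_length(land, 2)
  expect_equal(f_apart - f_joint, 2 * land$B[1, 2])
  expect_equal(f_joint, 4 + 4 - 2)
})

test_that("minimum representation is exact set cover and matches p=100, beta=0", {
  # identity presence: every taxon needs its own area
  R <- diag(4)
  dimnames(R) <- list(paste0("a", 1:4), LETTERS[1:4])
  land <- tiny_landscape(R)
  mr <- minimum_representation(land)
  expect_equal(mr$status, "optimal")
  expect_setequal(mr$areas, paste0("a", 1:4))
  expect_equal(mr$cost, 4)

  R2 <- rbind(a1 = c(A = 1, B = 1), a2 = c(A = 1, B = 0))
  mr2 <- minimum_representation(tiny_landscape(R2))
  expect_equal(mr2$areas, "a1")

  withr::with_seed(19, {
    for (rep in 1:3) {
      R3 <- matrix(rbinom(80, 1, 0.35), 8, 10,
                   dimnames = list(paste0("a", 1:8), paste0("s", 1:10)))
      R3[1, ] <- pmax(R3[1, ], 1)  # guarantee coverability
      cost <- sample(1:9, 8, replace = TRUE)
      land3 <- tiny_landscape(R3, cost = cost)
      mr3 <- minimum_representation(land3)
      sys3 <- unit_trivial_system(colnames(R3))
      bf <- brute_force_reserve(land3, sys3, 100)
      expect_equal(mr3$objective, bf$objective, tolerance = 1e-9)
      sol <- solve_reserve(land3, sys3, 100)
      expect_equal(sol$objective, mr3$objective, tolerance = 1e-9)
    }
  })
})

test_that("minimum representation names uncoverable taxa", {
  R <- rbind(a1 = c(A = 1, B = 0))
  mr <- minimum_representation(tiny_landscape(R))
  expect_equal(mr$status, "infeasible")
  expect_match(mr$diagnostics, "B")
})

test_that("the y split variables agree with independently recomputed separation", {
  spec <- synth_spec(seed = 23, n_taxa = 6, grid_dim = 3)
  system <- aggregate_trees(gen_tree_collection(spec))
  land <- gen_landscape(spec, beta = 1)
  sol <- solve_reserve(land, system, 90)
  expect_equal(sum(system$weights * sol$y), sol$sd, tolerance = 1e-9)
  expect_gte(sol$sd_pct, 90 - 1e-6)
})

test_that("cost-ratio sweep merges intervals and reports exact linear cost lines", {
  # 3 areas: urban a1 holds all taxa cheaply; rural pair {a2,a3} covers the
  # same taxa at higher flat cost. Change point computable by hand.
  R <- rbind(a1 = c(A = 1, B = 1), a2 = c(A = 1, B = 0),
             a3 = c(A = 0, B = 1))
  land <- landscape(R, cost = c(3, 3, 4), beta = 0,
                    urban = c(TRUE, FALSE, FALSE))
  sys <- unit_trivial_system(c("A", "B"))
  sw <- cost_ratio_sweep(land, sys, 100, ratios = seq(1, 6, by = 0.5))
  iv <- tidy(sw)
  expect_equal(nrow(iv), 2)
  # urban set costs 3*rho, rural set costs 7: lines cross at rho = 7/3
  expect_equal(iv$slope[1], 3)
  expect_equal(iv$intercept[1], 0)
  expect_equal(iv$slope[2], 0)
  expect_equal(iv$intercept[2], 7)
  expect_equal(iv$ratio_max[1], 2)
  expect_equal(iv$ratio_min[2], 2.5)
  expect_equal(iv$n_urban, c(1, 0))
})

test_that("a sweep without urban areas is a single flat interval", {
  R <- rbind(a1 = c(A = 1, B = 1), a2 = c(A = 1, B = 1))
  land <- landscape(R, cost = c(1, 2), beta = 0)
  sys <- unit_trivial_system(c("A", "B"))
  sw <- cost_ratio_sweep(land, sys, 100, ratios = c(1, 2, 3))
  expect_equal(nrow(sw$intervals), 1)
  expect_equal(sw$intervals$slope, 0)
})

test_that("accumulated-cost crossover: discrete and analytic modes agree", {
  ratios <- seq(1, 20, by = 0.1)
  # A cheap now but steep; B expensive now but flat
  a <- c(intercept = 0, slope = 6186)
  b <- c(intercept = 11482, slope = 0)
  disc <- accumulated_cost_crossover(a, b, ratios)
  ana <- accumulated_cost_crossover(a, b, ratios, mode = "analytic")
  expect_false(is.na(disc$crossover))
  expect_lte(abs(disc$crossover - ana$crossover), 0.1 + 1e-9)
  # the per-step costs of A only exceed B past rho = 1.856...; cumulative
  # crossover must come later than that
  expect_gt(disc$crossover, 11482 / 6186)

  same <- accumulated_cost_crossover(a, a, ratios)
  expect_true(is.na(same$crossover))

  never <- accumulated_cost_crossover(c(intercept = 0, slope = 1),
                                      c(intercept = 0, slope = 2), ratios)
  expect_true(is.na(never$crossover))
})

test_that("ties at a change point keep sweeps deterministic under lexicographic mode", {
  R <- rbind(a1 = c(A = 1, B = 1), a2 = c(A = 1, B = 1))
  land <- landscape(R, cost = c(2, 2), beta = 0,
                    urban = c(TRUE, FALSE))
  sys <- unit_trivial_system(c("A", "B"))
  sw <- cost_ratio_sweep(land, sys, 100, ratios = c(1, 2),
                         lexicographic = TRUE)
  # at rho = 1 the areas tie at cost 2; the lexicographic rule prefers the
  # set excluding the earlier area, so {a2} is reported at both ratios and
  # the sweep collapses to one flat interval
  expect_equal(nrow(sw$intervals), 1)
  expect_equal(sw$intervals$areas[[1]], "a2")
  expect_equal(sw$intervals$slope, 0)
})
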