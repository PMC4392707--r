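test_that("without a web and k = n the whole taxon set is selected", {
  ss <- toy_system()
  prob <- taxon_problem(ss, web = NULL, k = 4)
  sol <- solve_taxon(prob)
  expect_equal(sol$status, "optimal")
  expect_setequal(sol$taxa, ss$taxa)
  expect_equal(sol$sd, total_weight(ss))
  expect_equal(sol$relative_sd, 100)
})

test_that("the three-taxon chain behaves as enumeration predicts", {
  web <- chain_web()
  sys <- split_system(c("P", "H", "Q"), diag(3), c(1, 2, 4))

  # k = 2, forced Q: Q needs H, H then needs P, but k forbids all three
  p_inf <- taxon_problem(sys, web, k = 2, forced = "Q")
  s_inf <- solve_taxon(p_inf)
  expect_equal(s_inf$status, "infeasible")
  expect_match(s_inf$diagnostics, "Q")

  # k = 3 admits the full chain
  s_ok <- solve_taxon(taxon_problem(sys, web, k = 3, forced = "Q"))
  expect_setequal(s_ok$taxa, c("P", "H", "Q"))

  # k = 2 unforced: best viable pair
  s2 <- solve_taxon(taxon_problem(sys, web, k = 2))
  bf <- brute_force_taxon(sys, web, k = 2)
  expect_equal(s2$sd, bf$objective)
  expect_setequal(s2$taxa, c("P", "H"))
})

test_that("taxon ILP equals the enumeration oracle on random instances, with and without d", {
  for (seed in c(101, 102, 103)) {
    spec <- synth_spec(seed = seed, n_taxa = 8, n_layers = 3,
                       connectance = 0.5)
    system <- aggregate_trees(gen_tree_collection(spec))
    web <- gen_foodweb(spec)
    for (d in list(NULL, 50)) {
      k <- 4
      prob <- taxon_problem(system, web, k = k, d = d)
      sol <- solve_taxon(prob)
      bf <- brute_force_taxon(system, web, k = k, d = d)
      expect_equal(sol$status, "optimal")
      expect_equal(sol$sd, bf$objective, tolerance = 1e-9)
      if (is.null(d)) expect_true(is_viable(web, sol$taxa))
      else expect_true(is_d_viable(web, sol$taxa, d))
    }
  }
})

test_that("d = epsilon reproduces the plain-viability objective", {
  spec <- synth_spec(seed = 104, n_taxa = 8, n_layers = 3)
  system <- aggregate_trees(gen_tree_collection(spec))
  web <- gen_foodweb(spec)
  s_plain <- solve_taxon(taxon_problem(system, web, k = 5))
  s_eps <- solve_taxon(taxon_problem(system, web, k = 5, d = 1e-7))
  expect_equal(s_eps$sd, s_plain$sd, tolerance = 1e-9)
})

test_that("objective is monotone in k and non-increasing in d", {
  spec <- synth_spec(seed = 105, n_taxa = 9, n_layers = 3)
  system <- aggregate_trees(gen_tree_collection(spec))
  web <- gen_foodweb(spec)
  sd_k <- vapply(3:7, function(k) {
    solve_taxon(taxon_problem(system, web, k = k))$sd
  }, numeric(1))
  expect_true(all(diff(sd_k) >= -1e-9))
  sd_d <- vapply(c(1e-7, 30, 50, 80), function(d) {
    sol <- solve_taxon(taxon_problem(system, web, k = 5, d = d))
    if (identical(sol$status, "optimal")) sol$sd else 0
  }, numeric(1))
  expect_true(all(diff(sd_d) <= 1e-9))
})

test_that("forced taxa count toward k unless exempted", {
  sys <- split_system(LETTERS[1:4], diag(4), c(5, 1, 1, 1))
  prob <- taxon_problem(sys, web = NULL, k = 2, forced = c("B", "C"))
  sol <- solve_taxon(prob)
  expect_setequal(sol$taxa, c("B", "C"))
  prob2 <- taxon_problem(sys, web = NULL, k = 2, forced = c("B", "C"),
                         forced_exempt = TRUE)
  sol2 <- solve_taxon(prob2)
  expect_length(sol2$taxa, 4)
  expect_error(taxon_problem(sys, web = NULL, k = 1, forced = c("B", "C")),
               "forced")
})

test_that("unconstrained optimization flags preyless specialists that viability repairs", {
  # E is a specialist predator carrying huge SD weight; its only prey R is
  # diversity-poor, so the unconstrained optimum drops R and strands E
  taxa <- c("R", "E", "X", "Y", "Z")
  mem <- diag(5)
  sys <- split_system(taxa, mem, c(0.1, 10, 3, 3, 3))
  web <- food_web(data.frame(predator = "E", prey = "R"), taxa = taxa)
  prob <- taxon_problem(sys, web, k = 4)
  gap <- unconstrained_gap(prob)
  expect_equal(gap$unsupported, "E")
  expect_setequal(gap$unconstrained$taxa, c("E", "X", "Y", "Z"))
  expect_true(is_viable(web, gap$constrained$taxa))
  expect_gte(gap$sd_gap, 0)
  # repairing viability swaps the cheapest non-prey for R
  expect_equal(gap$sd_gap, 3 - 0.1)

  # when top-SD taxa are basal there is nothing to repair
  web2 <- food_web(data.frame(predator = "R", prey = "E"), taxa = taxa)
  gap2 <- unconstrained_gap(taxon_problem(sys, web2, k = 4))
  expect_equal(gap2$sd_gap, 0)
  expect_length(gap2$unsupported, 0)
})

test_that("solutions re-verify against the module-independent viability predicates", {
  spec <- synth_spec(seed = 106, n_taxa = 10, n_layers = 4)
  system <- aggregate_trees(gen_tree_collection(spec))
  web <- gen_foodweb(spec)
  sol <- solve_taxon(taxon_problem(system, web, k = 6, d = 30))
  expect_true(is_d_viable(web, sol$taxa, 30))
  td <- tidy(sol)
  expect_true(all(td$delta[!is.na(td$delta)] >= 0.3 - 1e-9))
  g <- glance(sol)
  expect_equal(g$n_taxa, length(sol$taxa))
  expect_equal(g$d, 30)
})

test_that("infeasible d-viability names unselectable predators", {
  web <- food_web(data.frame(predator = "Q", prey = "P",
                             proportion = 0.2), taxa = c("P", "Q"))
  sys <- split_system(c("P", "Q"), diag(2), c(1, 1))
  sol <- solve_taxon(taxon_problem(sys, web, k = 2, d = 30, forced = "Q"))
  expect_equal(sol$status, "infeasible")
  expect_match(sol$diagnostics, "unselectable")
})
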