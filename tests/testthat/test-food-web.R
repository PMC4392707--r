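test_that("food web construction derives prey sets and basal taxa, rejecting bad input", {
  web <- small_diet_web()
  expect_setequal(web$taxa, c("P", "H", "Q"))
  expect_equal(web$basal, "P")
  expect_setequal(web$prey[["Q"]], c("H", "P"))
  expect_true(web$has_diets)

  expect_error(food_web(data.frame(predator = "A", prey = "A")),
               "self-loop")
  expect_error(
    food_web(data.frame(predator = "A", prey = "B"), taxa = c("A", "C")),
    "unknown taxa")
})

test_that("validate_web reports diet-sum violations, cycles and unsupported taxa", {
  expect_true(validate_web(small_diet_web())$clean)

  bad <- food_web(data.frame(predator = c("Q", "Q"), prey = c("P", "H"),
                             proportion = c(0.5, 0.4)),
                  taxa = c("P", "H", "Q"))
  rep1 <- validate_web(bad)
  expect_equal(rep1$diet_sum_violations$predator, "Q")
  expect_equal(rep1$diet_sum_violations$diet_sum, 0.9)

  cyc <- food_web(data.frame(predator = c("A", "B"), prey = c("B", "A")))
  expect_warning(rep2 <- validate_web(cyc), "cycle")
  expect_length(rep2$cycles, 1)
  expect_error(food_web(data.frame(predator = c("A", "B"),
                                   prey = c("B", "A")), strict_dag = TRUE),
               "cycle")

  # D preys on nothing reachable: C unreachable from any basal taxon
  island <- food_web(data.frame(predator = "C", prey = "D"),
                     taxa = c("P", "C", "D"))
  expect_equal(validate_web(island)$unreachable, character(0))

  # unselectable predators under d%: total in-web diet below d
  part <- food_web(data.frame(predator = "Q", prey = "P",
                              proportion = 0.2), taxa = c("P", "Q"))
  expect_equal(validate_web(part, d = 30)$unselectable, "Q")
})

test_that("viability is basal-or-fed, evaluated locally", {
  web <- chain_web()
  expect_true(is_viable(web, c("P", "H")))
  expect_false(is_viable(web, "H"))
  expect_true(is_viable(web, character(0)))
  expect_true(is_viable(web, "P"))
  expect_false(is_viable(web, c("P", "Q")))
  expect_true(is_viable(web, c("P", "H", "Q")))
})

test_that("diet_score sums selected prey proportions and saturates at 1", {
  web <- small_diet_web()
  expect_equal(diet_score(web, "Q", "P"), 0.2)
  expect_equal(diet_score(web, "Q", c("P", "H")), 1)
  expect_equal(diet_score(web, "Q", character(0)), 0)
  expect_warning(s <- diet_score(web, "P", "H"), "basal")
  expect_equal(s, 1)
  expect_equal(diet_score(web, "Q", "P", base_credit = 0.5), 0.7)
})

test_that("d%-viability thresholds the conserved diet fraction", {
  web <- small_diet_web()
  expect_false(is_d_viable(web, c("P", "Q"), d = 30))
  expect_true(is_d_viable(web, c("P", "Q"), d = 20))
  expect_true(is_d_viable(web, c("P", "H", "Q"), d = 30))
  expect_true(is_d_viable(web, c("P", "H", "Q"), d = 100))
})

test_that("d%-viability reduces to plain viability as d -> 0+ (exhaustive)", {
  spec <- synth_spec(seed = 5, n_taxa = 6, n_layers = 3, connectance = 0.6)
  web <- gen_foodweb(spec)
  expect_true(all(web$edges$proportion > 0))
  for (s in all_subsets(web$taxa)) {
    expect_identical(is_d_viable(web, s, d = 1e-7), is_viable(web, s),
                     info = paste(s, collapse = ","))
  }
})

test_that("diet_score is monotone in the selection and bounded by 1", {
  spec <- synth_spec(seed = 9, n_taxa = 8, n_layers = 3)
  web <- gen_foodweb(spec)
  preds <- setdiff(web$taxa, web$basal)
  withr::with_seed(1, {
    for (i in 1:30) {
      s2 <- sample(web$taxa, sample(1:8, 1))
      s1 <- sample(s2, sample(seq_along(s2), 1))
      j <- sample(preds, 1)
      d1 <- diet_score(web, j, s1)
      d2 <- diet_score(web, j, s2)
      expect_lte(d1, d2 + 1e-12)
      expect_lte(d2, 1)
    }
  })
})

test_that("removing a basal taxon never repairs an inviable set", {
  spec <- synth_spec(seed = 13, n_taxa = 7, n_layers = 3)
  web <- gen_foodweb(spec)
  for (s in all_subsets(web$taxa, min_size = 1L)) {
    if (!is_viable(web, s)) {
      for (b in intersect(s, web$basal)) {
        expect_false(is_viable(web, setdiff(s, b)))
      }
    }
  }
})

test_that("equal_diets assigns 1/n per prey arrow", {
  web <- equal_diets(chain_web())
  expect_true(web$has_diets)
  expect_equal(diet_score(web, "Q", "H"), 1)
  W <- diet_matrix(web)
  expect_equal(W["H", "P"], 1)
  expect_equal(rowSums(W)[c("H", "Q")], c(H = 1, Q = 1))
})
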