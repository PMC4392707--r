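test_that("canonicalization anchors the first taxon at 0 and rejects degenerate vectors", {
  expect_equal(canonicalize_split(c(1, 0, 0, 1)), c(0L, 1L, 1L, 0L))
  expect_equal(canonicalize_split(c(0, 1, 1, 0)), c(0L, 1L, 1L, 0L))
  expect_error(canonicalize_split(c(1, 1, 1, 1)), "degenerate")
  expect_error(canonicalize_split(c(0, 0, 0)), "degenerate")
  # idempotent, and invariant under complementation
  for (i in 1:20) {
    m <- c(0, sample(0:1, 6, replace = TRUE), 1)  # never degenerate
    cm <- canonicalize_split(m)
    expect_identical(canonicalize_split(cm), cm)
    expect_identical(canonicalize_split(1 - m), cm)
  }
})

test_that("tree split extraction merges root edges and recovers all branch lengths", {
  ss <- splits_from_tree(toy_tree())
  expect_equal(n_splits(ss), 5)
  expect_equal(total_weight(ss), 13)
  td <- tidy(ss)
  w_of <- function(side) td$weight[td$side_small == side]
  expect_equal(w_of("A"), 1)
  expect_equal(w_of("B"), 2)
  expect_equal(w_of("C"), 3)
  expect_equal(w_of("D"), 4)
  expect_equal(td$weight[td$size_small == 2], 3)  # AB|CD: 1 + 2 across root

  cherry <- ape::read.tree(text = "(A:1,B:2);")
  sc <- splits_from_tree(cherry)
  expect_equal(n_splits(sc), 1)
  expect_equal(total_weight(sc), 3)

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  st <- splits_from_tree(star)
  expect_equal(n_splits(st), 3)
  expect_true(all(is_trivial_split(st)))
  expect_equal(st$weights, rep(1, 3))
})

test_that("splits_from_tree warns on missing branch lengths and rejects bad leaves", {
  topo <- ape::read.tree(text = "((A,B),(C,D));")
  expect_warning(ss <- splits_from_tree(topo), "branch lengths")
  expect_equal(total_weight(ss), 0)
  dup <- ape::read.tree(text = "((A:1,A:1):1,B:2);")
  expect_error(splits_from_tree(dup), "unique")
})

test_that("separates and sd_score follow the bipartition definition", {
  ss <- toy_system()
  ab_cd <- ss$splits[which(tidy(ss)$size_small == 2), ]
  expect_true(separates(ab_cd, c("A", "C"), taxa = ss$taxa))
  expect_false(separates(ab_cd, c("A", "B"), taxa = ss$taxa))
  triv_a <- ss$splits[which(tidy(ss)$side_small == "A"), ]
  expect_false(separates(triv_a, "A", taxa = ss$taxa))

  expect_equal(sd_score(ss, c("A", "B")), 3)
  expect_equal(sd_score(ss, c("A", "C")), 7)
  expect_equal(sd_score(ss, ss$taxa), total_weight(ss))
  expect_equal(sd_score(ss, character(0)), 0)
  expect_equal(sd_score(ss, "A"), 0)
})

test_that("pd_score equals sd_score on single-tree systems, exhaustively", {
  tr <- toy_tree()
  expect_equal(pd_score(tr, c("A", "C")), 7)
  expect_equal(pd_score(tr, c("A", "B", "C", "D")), 13)
  expect_warning(p1 <- pd_score(tr, "A"), "fewer than 2")
  expect_equal(p1, 0)

  withr::with_seed(42, {
    for (n in c(4, 6, 8)) {
      tree <- random_small_tree(n)
      ss <- splits_from_tree(tree)
      for (s in all_subsets(tree$tip.label, min_size = 2L)) {
        expect_equal(sd_score(ss, s), pd_score(tree, s), tolerance = 1e-9)
      }
    }
  })
})

test_that("sd_score is monotone under subset growth", {
  withr::with_seed(7, {
    tree <- random_small_tree(8)
    ss <- splits_from_tree(tree)
    for (i in 1:50) {
      s2 <- sample(tree$tip.label, sample(2:8, 1))
      s1 <- sample(s2, sample(seq_along(s2), 1))
      expect_lte(sd_score(ss, s1), sd_score(ss, s2) + 1e-12)
    }
  })
})

test_that("split extraction agrees with an independent bipartition routine", {
  # phangorn::as.splits lists one bipartition per edge; after canonical
  # merging its weights must match ours
  withr::with_seed(11, {
    for (i in 1:5) {
      tree <- ape::unroot(random_small_tree(7))
      ours <- splits_from_tree(tree)
      ph <- phangorn::as.splits(tree)
      phm <- as.matrix(ph)[, ours$taxa, drop = FALSE]
      phw <- attr(ph, "weights")
      keep <- apply(phm, 1, function(r) !all(r == r[1]))
      agg <- new.env()
      for (j in which(keep)) {
        key <- paste0(canonicalize_split(phm[j, ]), collapse = "")
        assign(key, (if (exists(key, agg)) get(key, agg) else 0) + phw[j],
               envir = agg)
      }
      ours_key <- apply(ours$splits, 1, paste0, collapse = "")
      expect_setequal(ls(agg), ours_key)
      for (k in ours_key) {
        expect_equal(get(k, agg), ours$weights[match(k, ours_key)],
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("tree aggregation modes pool weights as mean-with-zeros, sum and frequency", {
  tr <- toy_tree()
  same <- aggregate_trees(list(tr, tr), mode = "mean")
  one <- splits_from_tree(tr)
  expect_equal(sort(same$weights), sort(one$weights))
  expect_equal(total_weight(same), 13)

  # internal split AB|CD (w=2) in tree1 only; AC|BD (w=4) in tree2 only
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):2,(B:1,D:1):2);")
  agg <- aggregate_trees(list(t1, t2), mode = "mean")
  td <- tidy(agg)
  internal <- td[!td$trivial, ]
  expect_equal(nrow(internal), 2)
  expect_equal(sort(internal$weight), c(1, 2))

  fr <- aggregate_trees(list(t1, t2), mode = "frequency")
  expect_true(all(fr$weights >= 0 & fr$weights <= 1))
  tdf <- tidy(fr)
  expect_equal(tdf$weight[tdf$trivial], rep(1, 4))
  expect_equal(tdf$weight[!tdf$trivial], c(0.5, 0.5))

  sm <- aggregate_trees(list(t1, t2), mode = "sum")
  expect_equal(total_weight(sm), 6 + 8)

  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(aggregate_trees(list(t1, t3)), "E")
})

test_that("mean aggregation of identical copies reproduces the single tree", {
  withr::with_seed(3, {
    tree <- random_small_tree(6)
    agg <- aggregate_trees(rep(list(tree), 5), mode = "mean")
    one <- splits_from_tree(tree)
    key <- function(s) apply(s$splits, 1, paste0, collapse = "")
    expect_setequal(key(agg), key(one))
    expect_equal(agg$weights[order(key(agg))],
                 one$weights[order(key(one))], tolerance = 1e-9)
  })
})

test_that("relative_sd supports both denominator conventions", {
  ss <- toy_system()
  expect_equal(relative_sd(ss, ss$taxa), 100)
  expect_equal(relative_sd(ss, c("A", "B")), 100 * 3 / 13)
  # non-trivial denominator: only AB|CD (w=3) counts, and {A,B} misses it
  expect_equal(relative_sd(ss, c("A", "B"), denominator = "nontrivial"), 0)
  expect_equal(relative_sd(ss, c("A", "C"), denominator = "nontrivial"), 100)
})

test_that("duplicate splits are merged by weight summation", {
  expect_warning(
    ss <- split_system(c("A", "B", "C"),
                       rbind(c(0, 1, 1), c(1, 0, 0), c(0, 0, 1)),
                       c(1, 2, 5), warn_duplicates = TRUE),
    "merged")
  expect_equal(n_splits(ss), 2)
  expect_equal(sum(ss$weights), 8)
})
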