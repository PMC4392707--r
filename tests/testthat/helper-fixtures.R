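# Shared fixtures, built in code.

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
}

toy_system <- function() splits_from_tree(toy_tree())

# three-level chain: Q eats only H, H eats only P, P basal
chain_web <- function() {
  food_web(data.frame(predator = c("H", "Q"), prey = c("P", "H")))
}

# P basal; H -> P; Q -> {H (0.8), P (0.2)}
small_diet_web <- function() {
  food_web(data.frame(
    predator = c("H", "Q", "Q"),
    prey = c("P", "H", "P"),
    proportion = c(1, 0.8, 0.2)
  ))
}

unit_trivial_system <- function(taxa) {
  split_system(taxa, diag(length(taxa)), rep(1, length(taxa)))
}

# landscape over explicit presence rows; unit costs unless given
tiny_landscape <- function(R, cost = NULL, B = NULL, beta = 0,
                           urban = NULL) {
  if (is.null(cost)) cost <- rep(1, nrow(R))
  landscape(R, cost, B, beta = beta, urban = urban)
}

random_small_tree <- function(n) {
  ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
}

all_subsets <- function(x, min_size = 0L) {
  n <- length(x)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    if (length(idx) >= min_size) out[[length(out) + 1L]] <- x[idx]
  }
  out
}
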