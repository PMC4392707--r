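# Seeded synthetic-instance generators. These define the study conditions
# under which the package is validated: bootstrap-like tree collections
# over a common taxon set, grid landscapes with geometric boundary matrices
# and clustered (rectangular) species ranges, and layered acyclic food webs
# with Dirichlet diet rows summing to 1. The same seed always yields the
# bit-identical instance.

#' Specify a synthetic instance
#'
#' @param seed Integer seed; the instance is a deterministic function of it.
#' @param n_taxa Number of taxa (>= 3 for tree generation).
#' @param n_trees Trees in the bootstrap-like collection.
#' @param nni_moves Topological perturbation strength: number of random
#'   nearest-neighbor-interchange moves applied per replicate (0 =
#'   identical replicates).
#' @param jitter_sd Log-scale standard deviation of the multiplicative
#'   lognormal branch-length jitter per replicate.
#' @param grid_dim Landscape grid side length g (g x g unit cells,
#'   4-neighborhood, unit shared edges, perimeter 4).
#' @param range_frac Linear extent of a taxon's rectangular range as a
#'   fraction of the grid side (1 = every taxon everywhere).
#' @param urban_frac Fraction of the grid side forming the urban corner
#'   block.
#' @param cost_levels Integer unit prices sampled per cell (cost = cell
#'   area x unit price; cells have unit area).
#' @param n_layers Trophic layers of the food web (layer 1 basal).
#' @param connectance Probability that a consumer preys on any given taxon
#'   of the layers below it (at least one prey is guaranteed).
#' @param diet_conc Symmetric Dirichlet concentration for diet rows
#'   (1 = uniform on the simplex).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_taxa = 8L, n_trees = 10L,
                       nni_moves = 1L, jitter_sd = 0.2, grid_dim = 3L,
                       range_frac = 0.5, urban_frac = 0.5,
                       cost_levels = 1:5, n_layers = 3L,
                       connectance = 0.4, diet_conc = 1) {
  stopifnot(n_taxa >= 1L, n_trees >= 1L, nni_moves >= 0L, grid_dim >= 2L,
            n_layers >= 2L, connectance > 0, connectance <= 1,
            diet_conc > 0, range_frac > 0, range_frac <= 1)
  structure(
    list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
         n_trees = as.integer(n_trees), nni_moves = as.integer(nni_moves),
         jitter_sd = jitter_sd, grid_dim = as.integer(grid_dim),
         range_frac = range_frac, urban_frac = urban_frac,
         cost_levels = as.integer(cost_levels),
         n_layers = as.integer(n_layers), connectance = connectance,
         diet_conc = diet_conc),
    class = "synth_spec"
  )
}

synth_taxa <- function(spec) sprintf("t%02d", seq_len(spec$n_taxa))

#' Generate a bootstrap-like tree collection
#'
#' Draws a base tree (random topology with independent exponential branch
#' lengths, emulating a Yule-type process) and perturbs each replicate by
#' `nni_moves` random NNI moves plus multiplicative lognormal jitter of the
#' branch lengths — the kind of topological and length variation seen
#' across bootstrap replicates of a real alignment.
#'
#' @param spec A `synth_spec` (needs `n_taxa` >= 3).
#' @return A `multiPhylo` list of `n_trees` trees over a common taxon set.
#' @export
gen_tree_collection <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$n_taxa >= 3L)
  withr::with_seed(spec$seed, {
    base <- ape::rtree(spec$n_taxa, tip.label = synth_taxa(spec),
                       br = stats::rexp)
    trees <- lapply(seq_len(spec$n_trees), function(i) {
      tr <- base
      if (spec$nni_moves > 0L) {
        tr <- phangorn::rNNI(tr, moves = spec$nni_moves)
        if (spec$jitter_sd > 0) {
          tr$edge.length <- tr$edge.length *
            stats::rlnorm(length(tr$edge.length), 0, spec$jitter_sd)
        }
      }
      tr
    })
    structure(trees, class = "multiPhylo")
  })
}

grid_boundary <- function(g) {
  m <- g * g
  ids <- sprintf("a%02d", seq_len(m))
  B <- matrix(0, m, m, dimnames = list(ids, ids))
  diag(B) <- 4
  cell <- function(r, c) (r - 1L) * g + c
  for (r in seq_len(g)) {
    for (c in seq_len(g)) {
      i <- cell(r, c)
      if (c < g) B[i, cell(r, c + 1L)] <- B[cell(r, c + 1L), i] <- 1
      if (r < g) B[i, cell(r + 1L, c)] <- B[cell(r + 1L, c), i] <- 1
    }
  }
  B
}

#' Generate a grid landscape with clustered species ranges
#'
#' Unit cells on a g x g grid with a 4-neighborhood boundary matrix (shared
#' edges of length 1, perimeter 4). Each taxon occupies a random axis-
#' aligned rectangle of cells whose side is about `range_frac` of the grid,
#' emulating clustered geographic ranges; every range is non-empty by
#' construction. Urban cells form a corner block; costs are integer unit
#' prices (cell area 1).
#'
#' @param spec A `synth_spec`.
#' @param taxa Taxon labels (default the spec's standard labels).
#' @param beta Boundary cost rate stored in the landscape.
#' @return A `landscape`.
#' @export
gen_landscape <- function(spec, taxa = synth_taxa(spec), beta = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$grid_dim
  withr::with_seed(spec$seed + 1000L, {
    B <- grid_boundary(g)
    ids <- rownames(B)
    R <- matrix(0, g * g, length(taxa), dimnames = list(ids, taxa))
    side <- max(1L, round(g * spec$range_frac))
    for (j in seq_along(taxa)) {
      h <- sample(seq_len(side), 1L)
      w <- sample(seq_len(side), 1L)
      r0 <- sample(seq_len(g - h + 1L), 1L)
      c0 <- sample(seq_len(g - w + 1L), 1L)
      for (r in r0:(r0 + h - 1L)) {
        R[(r - 1L) * g + (c0:(c0 + w - 1L)), j] <- 1
      }
    }
    cost <- sample(spec$cost_levels, g * g, replace = TRUE)
    ub <- max(1L, round(g * spec$urban_frac))
    urban <- rep(FALSE, g * g)
    for (r in seq_len(ub)) urban[(r - 1L) * g + seq_len(ub)] <- TRUE
    landscape(R, cost, B, beta = beta, urban = urban)
  })
}

#' Generate a layered food web with Dirichlet diets
#'
#' Assigns taxa to `n_layers` trophic layers (layer 1 basal) and draws, for
#' each consumer, arrows to taxa in strictly lower layers with probability
#' `connectance` (at least one prey guaranteed), so the web is acyclic by
#' construction. Diet rows are drawn from a symmetric Dirichlet and sum to
#' 1 exactly.
#'
#' @param spec A `synth_spec`.
#' @param taxa Taxon labels (default the spec's standard labels).
#' @return A `food_web` with diet proportions.
#' @export
gen_foodweb <- function(spec, taxa = synth_taxa(spec)) {
  stopifnot(inherits(spec, "synth_spec"), length(taxa) >= 2L)
  L <- min(spec$n_layers, length(taxa))
  withr::with_seed(spec$seed + 2000L, {
    layer <- sort(rep_len(seq_len(L), length(taxa)))
    edges <- list()
    for (i in seq_along(taxa)) {
      if (layer[i] == 1L) next
      lower <- which(layer < layer[i])
      pick <- lower[stats::runif(length(lower)) < spec$connectance]
      if (length(pick) == 0L) pick <- sample(lower, 1L)
      gam <- stats::rgamma(length(pick), shape = spec$diet_conc)
      prop <- gam / sum(gam)
      prop[length(prop)] <- 1 - sum(prop[-length(prop)])
      edges[[length(edges) + 1L]] <- tibble::tibble(
        predator = taxa[i], prey = taxa[pick], proportion = prop)
    }
    food_web(dplyr::bind_rows(edges), taxa = taxa)
  })
}

#' Write a complete synthetic instance to a directory
#'
#' Emits the instance in the standard interchange formats: `trees.nwk`,
#' `splits.nex` (mean-aggregated system), `presence.csv`, `costs.csv`,
#' `boundary.csv` and `foodweb.tsv`.
#'
#' @param spec A `synth_spec`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_instance <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trees <- gen_tree_collection(spec)
  ape::write.tree(trees, file.path(dir, "trees.nwk"))
  system <- aggregate_trees(trees, mode = "mean")
  write_splits_nexus(system, file.path(dir, "splits.nex"))
  land <- gen_landscape(spec)
  pres <- tibble::as_tibble(land$R, rownames = "area")
  readr::write_csv(pres, file.path(dir, "presence.csv"))
  readr::write_csv(
    tibble::tibble(area = land$areas, cost = land$cost,
                   urban = as.integer(land$urban)),
    file.path(dir, "costs.csv"))
  readr::write_csv(tibble::as_tibble(land$B, rownames = "area"),
                   file.path(dir, "boundary.csv"))
  web <- gen_foodweb(spec)
  write_foodweb_tsv(web, file.path(dir, "foodweb.tsv"))
  invisible(dir)
}
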