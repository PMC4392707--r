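#' Canonicalize a split membership vector
#'
#' A split (bipartition) of a taxon set is encoded as a binary vector with
#' one entry per taxon; the vector and its complement describe the same
#' bipartition. The canonical form is the orientation in which the first
#' taxon carries value 0, so every split has exactly one representation.
#'
#' @param membership Integer, numeric or logical vector of 0/1 values, one
#'   per taxon, in the fixed taxon order.
#' @return An integer 0/1 vector in canonical orientation.
#' @examples
#' canonicalize_split(c(1, 0, 0, 1))  # -> 0 1 1 0
#' canonicalize_split(c(0, 1, 1, 0))  # unchanged
#' @export
canonicalize_split <- function(membership) {
  m <- as.integer(round(as.numeric(membership)))
  if (length(m) < 2L || anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("`membership` must be a binary vector of length >= 2", call. = FALSE)
  }
  if (all(m == m[1L])) {
    stop("degenerate split: both sides of a bipartition must be non-empty",
         call. = FALSE)
  }
  if (m[1L] == 1L) m <- 1L - m
  m
}

#' Construct a weighted split system
#'
#' A split system (Sigma, lambda) is a set of bipartitions of a fixed,
#' ordered taxon set together with a non-negative weight per split, in
#' branch-length units. Duplicate splits (after canonicalization) are merged
#' by summing their weights.
#'
#' @param taxa Character vector of unique, non-empty taxon labels. The order
#'   is frozen: canonical split orientation is anchored on the first taxon.
#' @param memberships A k x n binary matrix (rows are splits) or a list of
#'   binary vectors.
#' @param weights Numeric vector of k non-negative split weights.
#' @param warn_duplicates Warn when duplicate splits are merged.
#' @return An object of class `split_system` with fields `taxa`, `splits`
#'   (canonical 0/1 matrix with taxa as columns) and `weights`.
#' @export
split_system <- function(taxa, memberships, weights, warn_duplicates = FALSE) {
  taxa <- as.character(taxa)
  if (length(taxa) < 1L || anyDuplicated(taxa) || any(!nzchar(taxa)) || anyNA(taxa)) {
    stop("`taxa` must be unique non-empty labels", call. = FALSE)
  }
  if (is.list(memberships)) {
    memberships <- do.call(rbind, lapply(memberships, as.numeric))
  }
  memberships <- matrix(as.numeric(memberships), ncol = length(taxa))
  weights <- as.numeric(weights)
  if (nrow(memberships) != length(weights)) {
    stop("one weight per split is required", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("split weights must be finite and non-negative", call. = FALSE)
  }
  if (nrow(memberships) == 0L) {
    canon <- matrix(integer(0), 0L, length(taxa), dimnames = list(NULL, taxa))
    return(structure(list(taxa = taxa, splits = canon, weights = numeric(0)),
                     class = "split_system"))
  }
  canon <- t(apply(memberships, 1L, canonicalize_split))
  if (nrow(memberships) == 1L) canon <- matrix(canon, nrow = 1L)
  key <- apply(canon, 1L, paste0, collapse = "")
  if (anyDuplicated(key)) {
    if (warn_duplicates) {
      warning("duplicate splits merged by summing weights", call. = FALSE)
    }
    weights <- as.numeric(tapply(weights, key, sum)[unique(key)])
    canon <- canon[!duplicated(key), , drop = FALSE]
  }
  dimnames(canon) <- list(NULL, taxa)
  structure(
    list(taxa = taxa, splits = canon, weights = as.numeric(weights)),
    class = "split_system"
  )
}

#' @export
print.split_system <- function(x, ...) {
  cat("Split system over", length(x$taxa), "taxa:",
      nrow(x$splits), "splits, total weight",
      format(sum(x$weights)), "\n")
  invisible(x)
}

#' Number of splits in a split system
#' @param system A `split_system`.
#' @export
n_splits <- function(system) nrow(system$splits)

#' Total weight (SD of the full taxon set)
#' @param system A `split_system`.
#' @export
total_weight <- function(system) sum(system$weights)

#' Identify trivial splits
#'
#' A trivial split separates a single taxon from all others. Trivial splits
#' carry the pendant branch lengths and are retained throughout: they are
#' required for the PD equivalence and make a 100% SD target imply full
#' taxon coverage.
#'
#' @param system A `split_system`.
#' @return Logical vector, one entry per split.
#' @export
is_trivial_split <- function(system) {
  rs <- rowSums(system$splits)
  rs == 1 | rs == (length(system$taxa) - 1)
}

#' Tidy a split system into a tibble
#'
#' @param x A `split_system`.
#' @param ... Unused.
#' @return A tibble with one row per split: `split` (id), `weight`,
#'   `trivial`, `side_small` (comma-separated labels of the smaller side)
#'   and `size_small`.
#' @export
tidy.split_system <- function(x, ...) {
  rs <- rowSums(x$splits)
  n <- length(x$taxa)
  side <- vapply(seq_len(nrow(x$splits)), function(i) {
    m <- x$splits[i, ]
    lab <- if (rs[i] <= n - rs[i]) x$taxa[m == 1] else x$taxa[m == 0]
    paste(lab, collapse = ",")
  }, character(1))
  tibble::tibble(
    split = seq_len(nrow(x$splits)),
    weight = x$weights,
    trivial = is_trivial_split(x),
    side_small = side,
    size_small = pmin(rs, n - rs)
  )
}

resolve_subset <- function(taxa, subset) {
  if (is.character(subset)) {
    idx <- match(subset, taxa)
    if (anyNA(idx)) {
      stop("unknown taxa: ", paste(subset[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(subset)
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(taxa))) {
      stop("taxon indices out of range", call. = FALSE)
    }
  }
  unique(idx)
}

#' Does a split separate a taxon subset?
#'
#' TRUE iff the subset has at least one taxon on each side of the split,
#' i.e. the split contributes to the subset's diversity.
#'
#' @param split Binary membership vector (any orientation).
#' @param subset Taxon indices or labels.
#' @param taxa Taxon labels (needed when `subset` is character).
#' @export
separates <- function(split, subset, taxa = NULL) {
  m <- as.integer(round(as.numeric(split)))
  idx <- if (is.character(subset)) {
    resolve_subset(taxa, subset)
  } else {
    as.integer(subset)
  }
  s <- sum(m[idx])
  s >= 1L && s <= length(idx) - 1L
}

#' Split diversity of a taxon subset
#'
#' SD(S) is the summed weight of all splits that separate at least two taxa
#' of S. It equals 0 for the empty set and singletons, and the total split
#' weight for the full taxon set. On the split system of a single tree it
#' coincides with Faith's phylogenetic diversity of the unrooted tree.
#'
#' @param system A `split_system`.
#' @param subset Taxon labels or indices.
#' @return Non-negative scalar in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
#' ss <- splits_from_tree(tr)
#' sd_score(ss, c("A", "B"))  # 3
#' sd_score(ss, c("A", "C"))  # 7
#' @export
sd_score <- function(system, subset) {
  idx <- resolve_subset(system$taxa, subset)
  if (length(idx) < 2L) return(0)
  s <- system$splits[, idx, drop = FALSE]
  rs <- rowSums(s)
  sep <- rs >= 1 & rs <= length(idx) - 1
  sum(system$weights[sep])
}

#' Phylogenetic diversity of a taxon subset
#'
#' Unrooted PD: the sum of branch lengths of the minimal subtree of the
#' (unrooted) tree spanning the subset. Computed directly on the tree via
#' subtree extraction, independently of any split machinery, so it doubles
#' as an oracle for [sd_score()] on single-tree split systems.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param subset Taxon labels or indices (into `tree$tip.label`).
#' @return Non-negative scalar; 0 with a warning for subsets of size < 2.
#' @export
pd_score <- function(tree, subset) {
  stopifnot(inherits(tree, "phylo"))
  idx <- resolve_subset(tree$tip.label, subset)
  if (length(idx) < 2L) {
    warning("PD of a subset with fewer than 2 taxa is defined as 0",
            call. = FALSE)
    return(0)
  }
  labs <- tree$tip.label[idx]
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (length(idx) == length(tr$tip.label)) return(sum(tr$edge.length))
  sub <- ape::keep.tip(tr, labs)
  sum(sub$edge.length)
}

#' Extract the split system of a phylogenetic tree
#'
#' Every edge of the unrooted tree induces a bipartition of the taxa; its
#' weight is the branch length. Rooted trees are implicitly unrooted: the
#' two root-incident edges induce the same bipartition and are merged by
#' summing their lengths. Trivial splits (pendant edges) are retained.
#' Missing branch lengths default to 0 with a warning, so topology-only
#' trees remain usable for frequency-based aggregation.
#'
#' @param tree An `ape::phylo` tree with >= 2 uniquely labeled leaves.
#' @param taxa Optional taxon label order for the resulting system; must be
#'   a permutation of `tree$tip.label`. Defaults to the tree's own order.
#' @return A `split_system`. Its total weight equals the sum of all branch
#'   lengths of the tree.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
#' splits_from_tree(tr)  # 5 splits, total weight 13
#' @export
splits_from_tree <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.null(tips) || length(tips) < 2L) {
    stop("tree must have at least 2 labeled leaves", call. = FALSE)
  }
  if (anyDuplicated(tips) || any(!nzchar(tips))) {
    stop("tree leaves must carry unique non-empty labels", call. = FALSE)
  }
  if (is.null(taxa)) {
    taxa <- tips
  } else if (!setequal(taxa, tips) || length(taxa) != length(tips)) {
    stop("`taxa` must be a permutation of the tree's tip labels",
         call. = FALSE)
  }
  n <- length(taxa)
  el <- tree$edge.length
  if (is.null(el)) {
    warning("tree has no branch lengths; all split weights set to 0",
            call. = FALSE)
    el <- rep(0, nrow(tree$edge))
  }
  if (anyNA(el)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    el[is.na(el)] <- 0
  }
  if (any(el < 0)) stop("negative branch lengths", call. = FALSE)

  tr <- tree
  tr$edge.length <- el
  tr <- stats::reorder(tr, "postorder")
  nnode <- max(tr$edge)
  below <- matrix(FALSE, nnode, n)
  below[cbind(seq_len(n), match(tips, taxa))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  mem <- below[tr$edge[, 2L], , drop = FALSE] * 1
  w <- tr$edge.length
  full <- rowSums(mem) == n
  if (any(full)) {
    # an edge above the whole taxon set (single-child root) carries no
    # bipartition information
    if (any(w[full] > 0)) {
      warning("dropping root edge spanning all taxa (weight ",
              format(sum(w[full])), ")", call. = FALSE)
    }
    mem <- mem[!full, , drop = FALSE]
    w <- w[!full]
  }
  split_system(taxa, mem, w)
}

#' Aggregate the splits of a tree collection into one split system
#'
#' Pools the edge bipartitions of several trees over a common taxon set
#' (e.g. bootstrap replicates or gene trees) into a single weighted split
#' system, the substrate for split diversity.
#'
#' @param trees A list of `ape::phylo` trees or a `multiPhylo`; all trees
#'   must share one taxon set.
#' @param mode Weighting scheme: `"mean"` (default) averages each split's
#'   branch length over all trees, counting 0 where a tree lacks the split,
#'   so SD is an expectation over the tree collection; `"sum"` leaves the
#'   pooled lengths unnormalized; `"frequency"` weights each split by the
#'   fraction of trees containing it (weights in \[0, 1\]).
#' @return A `split_system` over the first tree's taxon order.
#' @export
aggregate_trees <- function(trees, mode = c("mean", "sum", "frequency")) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) < 1L) stop("at least one tree required", call. = FALSE)
  taxa <- trees[[1L]]$tip.label
  for (i in seq_along(trees)) {
    ti <- trees[[i]]$tip.label
    if (!setequal(ti, taxa) || length(ti) != length(taxa)) {
      extra <- setdiff(ti, taxa)
      miss <- setdiff(taxa, ti)
      stop("tree ", i, " taxon set mismatch; only in tree ", i, ": {",
           paste(extra, collapse = ", "), "}; missing from tree ", i, ": {",
           paste(miss, collapse = ", "), "}", call. = FALSE)
    }
  }
  ntree <- length(trees)
  acc_w <- new.env(parent = emptyenv())
  acc_n <- new.env(parent = emptyenv())
  acc_m <- new.env(parent = emptyenv())
  for (tr in trees) {
    ss <- splits_from_tree(tr, taxa = taxa)
    keys <- apply(ss$splits, 1L, paste0, collapse = "")
    for (j in seq_along(keys)) {
      k <- keys[j]
      assign(k, (if (exists(k, acc_w)) get(k, acc_w) else 0) + ss$weights[j],
             envir = acc_w)
      assign(k, (if (exists(k, acc_n)) get(k, acc_n) else 0L) + 1L,
             envir = acc_n)
      if (!exists(k, acc_m)) assign(k, ss$splits[j, ], envir = acc_m)
    }
  }
  keys <- sort(ls(acc_w))
  mem <- do.call(rbind, lapply(keys, get, envir = acc_m))
  w <- switch(mode,
    mean = vapply(keys, get, numeric(1), envir = acc_w) / ntree,
    sum = vapply(keys, get, numeric(1), envir = acc_w),
    frequency = vapply(keys, function(k) get(k, acc_n), integer(1)) / ntree
  )
  split_system(taxa, mem, as.numeric(w))
}

#' Split diversity of a subset relative to the whole system
#'
#' @param system A `split_system`.
#' @param subset Taxon labels or indices.
#' @param denominator Either `"all"` (default; relative to the total weight
#'   of all splits) or `"nontrivial"` (both the score and the denominator
#'   drop trivial splits).
#' @return Percentage in \[0, 100\].
#' @export
relative_sd <- function(system, subset, denominator = c("all", "nontrivial")) {
  denominator <- match.arg(denominator)
  if (denominator == "nontrivial") {
    keep <- !is_trivial_split(system)
    system <- split_system(system$taxa, system$splits[keep, , drop = FALSE],
                           system$weights[keep])
  }
  tot <- total_weight(system)
  if (tot == 0) return(0)
  100 * sd_score(system, subset) / tot
}
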