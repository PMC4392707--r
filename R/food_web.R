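#' Construct a food web from a predator-prey edge list
#'
#' A food web is a directed graph whose arrows point from predator to prey.
#' Taxa without prey are *basal* (e.g. primary producers). An optional
#' `proportion` column gives the diet composition: the fraction of prey i in
#' the diet of predator j, which should sum to 1 over each predator's prey.
#'
#' @param edges Data frame with character columns `predator` and `prey` and
#'   an optional numeric `proportion` column.
#' @param taxa Taxon labels; defaults to the labels appearing in `edges`, in
#'   order of first appearance. Taxa absent from `edges` are basal.
#' @param strict_dag Reject webs containing directed cycles instead of
#'   merely warning in [validate_web()].
#' @return An object of class `food_web` with fields `taxa`, `edges`
#'   (tibble), `prey` (named list of prey sets), `basal` (character) and
#'   `has_diets`.
#' @examples
#' web <- food_web(data.frame(
#'   predator = c("H", "Q", "Q"), prey = c("P", "H", "P"),
#'   proportion = c(1, 0.8, 0.2)
#' ))
#' is_viable(web, c("P", "H"))
#' @export
food_web <- function(edges, taxa = NULL, strict_dag = FALSE) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("predator", "prey") %in% names(edges))) {
    stop("`edges` needs columns `predator` and `prey`", call. = FALSE)
  }
  edges$predator <- as.character(edges$predator)
  edges$prey <- as.character(edges$prey)
  seen <- unique(c(rbind(edges$predator, edges$prey)))
  if (is.null(taxa)) {
    taxa <- seen
  } else {
    taxa <- as.character(taxa)
    unknown <- setdiff(seen, taxa)
    if (length(unknown) > 0L) {
      stop("food-web arrow references unknown taxa: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon labels", call. = FALSE)
  if (any(edges$predator == edges$prey)) {
    stop("self-loops (a taxon preying on itself) are not allowed",
         call. = FALSE)
  }
  if (anyDuplicated(edges[c("predator", "prey")])) {
    stop("duplicate predator-prey arrows", call. = FALSE)
  }
  has_diets <- "proportion" %in% names(edges)
  if (has_diets) {
    edges$proportion <- as.numeric(edges$proportion)
    if (anyNA(edges$proportion) || any(edges$proportion < 0) ||
        any(edges$proportion > 1)) {
      stop("diet proportions must lie in [0, 1]", call. = FALSE)
    }
  }
  prey <- lapply(stats::setNames(taxa, taxa), function(t) {
    edges$prey[edges$predator == t]
  })
  basal <- taxa[lengths(prey) == 0L]
  web <- structure(
    list(taxa = taxa, edges = edges, prey = prey, basal = basal,
         has_diets = has_diets),
    class = "food_web"
  )
  if (strict_dag && length(web_cycles(web)) > 0L) {
    stop("food web contains directed cycles (strict_dag = TRUE)",
         call. = FALSE)
  }
  web
}

#' @export
print.food_web <- function(x, ...) {
  cat("Food web:", length(x$taxa), "taxa,", nrow(x$edges), "arrows,",
      length(x$basal), "basal",
      if (x$has_diets) "(with diet proportions)" else "(unweighted)", "\n")
  invisible(x)
}

web_igraph <- function(web) {
  igraph::graph_from_data_frame(
    web$edges[c("predator", "prey")],
    directed = TRUE,
    vertices = data.frame(name = web$taxa)
  )
}

web_cycles <- function(web) {
  g <- web_igraph(web)
  if (igraph::is_dag(g)) return(list())
  comp <- igraph::components(g, mode = "strong")
  idx <- which(tabulate(comp$membership) > 1L)
  lapply(idx, function(i) web$taxa[comp$membership == i])
}

#' Diet composition matrix of a food web
#'
#' @param web A `food_web` with diet proportions.
#' @return An n x n matrix `W` with `W[j, i]` the proportion of prey i in
#'   the diet of predator j; rows of basal taxa are all zero.
#' @export
diet_matrix <- function(web) {
  if (!web$has_diets) stop("food web carries no diet proportions",
                           call. = FALSE)
  n <- length(web$taxa)
  W <- matrix(0, n, n, dimnames = list(web$taxa, web$taxa))
  W[cbind(web$edges$predator, web$edges$prey)] <- web$edges$proportion
  W
}

#' Assign equal diet proportions to an unweighted web
#'
#' Gives every arrow of predator j the weight 1/|C_j|, the usual fallback
#' when only topological food-web data are available.
#'
#' @param web A `food_web`.
#' @return The web with a `proportion` column added (or replaced).
#' @export
equal_diets <- function(web) {
  deg <- lengths(web$prey)[web$edges$predator]
  web$edges$proportion <- 1 / as.numeric(deg)
  web$has_diets <- TRUE
  web
}

#' Validate a food web and its diet composition
#'
#' Collects structural diagnostics without failing: directed cycles (a
#' warning, since the local viability constraints remain well-defined under
#' omnivory loops), diet rows that do not sum to 1, taxa unreachable from
#' any basal taxon, and — when `d` is given — predators whose total in-web
#' diet falls below d/100 and are therefore unselectable under d%-viability.
#'
#' @param web A `food_web`.
#' @param d Optional viability threshold in percent, see [is_d_viable()].
#' @param tol Tolerance for the diet sum-to-1 check.
#' @return A list of class `web_report` with elements `cycles`,
#'   `diet_sum_violations` (tibble), `unreachable`, `unselectable` and
#'   `clean` (logical: no findings).
#' @export
validate_web <- function(web, d = NULL, tol = 1e-6) {
  stopifnot(inherits(web, "food_web"))
  cycles <- web_cycles(web)
  if (length(cycles) > 0L) {
    warning("food web contains directed cycles: ",
            paste(vapply(cycles, paste, "", collapse = "<->"),
                  collapse = "; "), call. = FALSE)
  }
  sums <- tibble::tibble(predator = character(0), diet_sum = numeric(0))
  if (web$has_diets) {
    agg <- tapply(web$edges$proportion, web$edges$predator, sum)
    bad <- abs(agg - 1) > tol
    sums <- tibble::tibble(predator = names(agg)[bad],
                           diet_sum = as.numeric(agg[bad]))
  }
  if (length(web$basal) == 0L) {
    unreachable <- setdiff(web$taxa, character(0))
  } else {
    g <- web_igraph(web)
    # arrows point predator -> prey, so reachability *to* a basal taxon
    reach <- igraph::distances(g, to = web$basal, mode = "out")
    unreachable <- web$taxa[apply(is.infinite(reach), 1L, all)]
    unreachable <- setdiff(unreachable, web$basal)
  }
  unselectable <- character(0)
  if (!is.null(d)) {
    if (!web$has_diets) stop("d%-viability needs diet proportions",
                             call. = FALSE)
    tot <- tapply(web$edges$proportion, web$edges$predator, sum)
    unselectable <- names(tot)[tot < d / 100 - 1e-9]
  }
  structure(
    list(cycles = cycles, diet_sum_violations = sums,
         unreachable = unreachable, unselectable = unselectable,
         clean = length(cycles) == 0L && nrow(sums) == 0L &&
           length(unreachable) == 0L && length(unselectable) == 0L),
    class = "web_report"
  )
}

#' @export
print.web_report <- function(x, ...) {
  if (x$clean) {
    cat("Food web OK: no cycles, diet sums consistent, all taxa supported\n")
  } else {
    if (length(x$cycles)) cat("Cycles:", length(x$cycles), "\n")
    if (nrow(x$diet_sum_violations))
      cat("Diet rows not summing to 1:",
          paste(x$diet_sum_violations$predator, collapse = ", "), "\n")
    if (length(x$unreachable))
      cat("Unreachable from basal taxa:",
          paste(x$unreachable, collapse = ", "), "\n")
    if (length(x$unselectable))
      cat("Unselectable under d%-viability:",
          paste(x$unselectable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Is a taxon subset viable in a food web?
#'
#' A taxon is viable in S if it is basal (has no prey in the web) or has at
#' least one of its prey in S; S is viable if all its members are. The empty
#' set is vacuously viable.
#'
#' @param web A `food_web`.
#' @param subset Taxon labels.
#' @export
is_viable <- function(web, subset) {
  subset <- as.character(subset)
  unknown <- setdiff(subset, web$taxa)
  if (length(unknown)) stop("unknown taxa: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  all(vapply(subset, function(t) {
    t %in% web$basal || length(intersect(web$prey[[t]], subset)) > 0L
  }, logical(1)))
}

#' Conserved diet fraction of a predator
#'
#' delta(s_j | S): the summed diet proportion of predator j contributed by
#' its prey taxa inside S. Raw sums over the web's listed prey; prey
#' consumed outside the web can be acknowledged through a constant
#' `base_credit` added to every predator's score (default 0).
#'
#' @param web A `food_web` with diet proportions.
#' @param predator A single taxon label.
#' @param subset Taxon labels.
#' @param base_credit Diet fraction credited regardless of the selection.
#' @return A value in \[0, 1\]; basal taxa score 1 with a warning.
#' @export
diet_score <- function(web, predator, subset, base_credit = 0) {
  if (!web$has_diets) stop("food web carries no diet proportions",
                           call. = FALSE)
  stopifnot(length(predator) == 1L, predator %in% web$taxa)
  if (predator %in% web$basal) {
    warning("diet score of a basal taxon is defined as 1", call. = FALSE)
    return(1)
  }
  e <- web$edges[web$edges$predator == predator &
                   web$edges$prey %in% subset, ]
  min(1, base_credit + sum(e$proportion))
}

#' Is a taxon subset d%-viable?
#'
#' S is d%-viable if every non-basal member j retains at least d% of its
#' diet composition among the selected prey: delta(s_j | S) >= d/100. As
#' d tends to 0+ this reduces to plain viability ([is_viable()]) on webs
#' with strictly positive diet weights.
#'
#' @param web A `food_web` with diet proportions.
#' @param subset Taxon labels.
#' @param d Threshold in percent, 0 < d <= 100 (d = 30 means 30%).
#' @param base_credit See [diet_score()].
#' @param tol Numerical slack, relative to the threshold d/100, so the
#'   comparison stays sharp for arbitrarily small d (a predator with no
#'   selected prey fails for every d > 0).
#' @export
is_d_viable <- function(web, subset, d, base_credit = 0, tol = 1e-9) {
  stopifnot(is.numeric(d), length(d) == 1L, d > 0, d <= 100)
  subset <- as.character(subset)
  unknown <- setdiff(subset, web$taxa)
  if (length(unknown)) stop("unknown taxa: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  preds <- setdiff(subset, web$basal)
  all(vapply(preds, function(j) {
    diet_score(web, j, subset, base_credit = base_credit) >=
      (d / 100) * (1 - tol)
  }, logical(1)))
}
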