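# Enumeration oracles: independent ground truth for the ILP formulations on
# small instances. Deliberately written against the plain predicates
# (sd_score, is_viable, is_d_viable, fence_length), not the model builders.

#' Scaled-integer split weights and p% threshold
#'
#' In exact-threshold mode split weights are scaled by 1e6 and rounded to
#' integers, and the p% right-hand side becomes the smallest integer not
#' below (p/100) * total, so that "at least p% of SD" is never lost to
#' floating-point dust. Both the ILP builder and the enumeration oracle use
#' this helper, guaranteeing they test the same threshold.
#'
#' @param system A `split_system`.
#' @param p Percentage of total SD to preserve, in \[0, 100\].
#' @param scaled_integer Use the integer-scaled mode (default TRUE).
#' @return List with `weights` (per split) and `threshold`.
#' @export
sd_threshold <- function(system, p, scaled_integer = TRUE) {
  stopifnot(p >= 0, p <= 100)
  if (scaled_integer) {
    w <- round(system$weights * 1e6)
    thr <- ceiling(p * sum(w) / 100 - 1e-6)
  } else {
    w <- system$weights
    thr <- p * sum(w) / 100
  }
  list(weights = w, threshold = thr)
}

sd_of_subset_weighted <- function(system, weights, idx) {
  if (length(idx) < 2L) return(0)
  s <- system$splits[, idx, drop = FALSE]
  rs <- rowSums(s)
  sum(weights[rs >= 1 & rs <= length(idx) - 1])
}

#' Brute-force oracle for reserve selection
#'
#' Enumerates all 2^m area subsets, keeps those whose covered taxa attain at
#' least p% of total SD, and returns the minimum of cost + beta * fence.
#' Ground truth for [solve_reserve()] on small instances.
#'
#' @param land A `landscape` (at most 15 areas).
#' @param system A `split_system` over the landscape's taxa.
#' @param p Percentage of total SD to preserve.
#' @param scaled_integer See [sd_threshold()].
#' @return List with `areas` (character), `objective`, `sd` and `feasible`
#'   (FALSE when no subset attains the target).
#' @export
brute_force_reserve <- function(land, system, p, scaled_integer = TRUE) {
  m <- length(land$areas)
  if (m > 15L) stop("refusing enumeration for more than 15 areas",
                    call. = FALSE)
  th <- sd_threshold(system, p, scaled_integer)
  tx <- match(system$taxa, land$taxa)
  if (anyNA(tx)) stop("system taxa missing from landscape", call. = FALSE)
  best <- Inf
  best_set <- NULL
  best_sd <- NA_real_
  for (mask in 0:(2^m - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    cov <- if (length(idx)) which(colSums(land$R[idx, , drop = FALSE]) > 0)
           else integer(0)
    cov_sys <- match(land$taxa[cov], system$taxa)
    cov_sys <- cov_sys[!is.na(cov_sys)]
    val <- sd_of_subset_weighted(system, th$weights, cov_sys)
    if (val >= th$threshold - 1e-9) {
      obj <- sum(land$cost[idx]) + land$beta * fence_length(land, idx)
      if (obj < best - 1e-12) {
        best <- obj
        best_set <- land$areas[idx]
        best_sd <- sd_of_subset_weighted(system, system$weights, cov_sys)
      }
    }
  }
  if (is.infinite(best)) {
    return(list(areas = NULL, objective = NA_real_, sd = NA_real_,
                feasible = FALSE))
  }
  list(areas = best_set, objective = best, sd = best_sd, feasible = TRUE)
}

#' Brute-force oracle for (d%-)viable taxon selection
#'
#' Enumerates every subset of at most k taxa that contains the forced taxa,
#' filters by the viability predicate ([is_viable()], or [is_d_viable()]
#' when `d` is given), and returns the subset of maximal split diversity.
#' Ground truth for [solve_taxon()] on small instances.
#'
#' @param system A `split_system`.
#' @param web Optional `food_web` over the same taxa (NULL: no viability
#'   constraint).
#' @param k Maximum subset size.
#' @param d Optional diet threshold in percent.
#' @param forced Taxa that must be included.
#' @param base_credit See [diet_score()].
#' @return List with `taxa`, `objective` (SD) and `feasible`.
#' @export
brute_force_taxon <- function(system, web = NULL, k, d = NULL,
                              forced = character(0), base_credit = 0) {
  n <- length(system$taxa)
  if (n > 20L) stop("refusing enumeration for more than 20 taxa",
                    call. = FALSE)
  forced <- as.character(forced)
  stopifnot(all(forced %in% system$taxa), length(forced) <= k)
  free <- setdiff(system$taxa, forced)
  ok <- function(s) {
    if (is.null(web)) return(TRUE)
    if (is.null(d)) is_viable(web, s)
    else is_d_viable(web, s, d, base_credit = base_credit)
  }
  best <- -Inf
  best_set <- NULL
  for (extra in 0:(min(k - length(forced), length(free)))) {
    combos <- if (extra == 0L) list(character(0)) else
      utils::combn(free, extra, simplify = FALSE)
    for (cmb in combos) {
      s <- c(forced, cmb)
      if (!ok(s)) next
      val <- sd_score(system, s)
      if (val > best + 1e-12) {
        best <- val
        best_set <- s
      }
    }
  }
  if (is.infinite(best)) {
    return(list(taxa = NULL, objective = NA_real_, feasible = FALSE))
  }
  list(taxa = best_set, objective = best, feasible = TRUE)
}
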