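#' Define a (d%-)viable taxon-selection problem
#'
#' Bundles a split system, a food web over the same taxa, the subset-size
#' budget k, an optional diet threshold d (in percent) and taxa forced into
#' every solution (e.g. aggregate trophic groups at the base of the web).
#'
#' @param system A `split_system`.
#' @param web A `food_web` over the same taxon set, or NULL for
#'   unconstrained SD maximization.
#' @param k Maximum number of selected taxa.
#' @param d Optional threshold in percent (0 < d <= 100): every selected
#'   predator must retain at least d% of its diet. NULL selects the plain
#'   one-prey viability constraint.
#' @param forced Taxa fixed into the solution.
#' @param forced_exempt If TRUE, forced taxa do not count toward k.
#' @param base_credit Diet fraction credited to every predator regardless
#'   of the selection; see [diet_score()].
#' @return An object of class `taxon_problem`.
#' @export
taxon_problem <- function(system, web = NULL, k, d = NULL,
                          forced = character(0), forced_exempt = FALSE,
                          base_credit = 0) {
  stopifnot(inherits(system, "split_system"))
  if (!is.null(web)) {
    stopifnot(inherits(web, "food_web"))
    if (!setequal(web$taxa, system$taxa)) {
      stop("food web and split system must cover the same taxa; ",
           "differ on: ",
           paste(c(setdiff(web$taxa, system$taxa),
                   setdiff(system$taxa, web$taxa)), collapse = ", "),
           call. = FALSE)
    }
  }
  forced <- as.character(forced)
  stopifnot(all(forced %in% system$taxa))
  k <- as.integer(k)
  stopifnot(k >= 0)
  if (!forced_exempt && length(forced) > k) {
    stop("more forced taxa than the budget k allows", call. = FALSE)
  }
  if (!is.null(d)) {
    stopifnot(is.numeric(d), d > 0, d <= 100)
    if (is.null(web) || !web$has_diets) {
      stop("d%-viability requires a food web with diet proportions",
           call. = FALSE)
    }
  }
  structure(
    list(system = system, web = web, k = k, d = d, forced = forced,
         forced_exempt = forced_exempt, base_credit = base_credit),
    class = "taxon_problem"
  )
}

#' Build the ILP for (d%-)viable taxon selection under SD
#'
#' Maximizes sum lambda_sigma y_sigma over taxon variables v_i and split
#' variables y_sigma, subject to: at most k selected taxa; y_sigma bounded
#' above by the number of selected taxa on each side of the split (so a
#' split only counts when it separates the selection); and per non-basal
#' taxon j either the plain viability constraint v_j <= sum of v over j's
#' prey, or with a diet threshold the constraint
#' sum_i w_ji v_i >= (d/100) v_j. Forced taxa are fixed at 1.
#'
#' @param problem A `taxon_problem`.
#' @return An `ilp_model` with a `var_map` attribute.
#' @export
build_taxon_model <- function(problem) {
  stopifnot(inherits(problem, "taxon_problem"))
  sys <- problem$system
  n <- length(sys$taxa)
  vv <- paste0("v_", seq_len(n))
  names(vv) <- sys$taxa
  nspl <- n_splits(sys)
  yv <- if (nspl) paste0("y_", seq_len(nspl)) else character(0)
  cons <- list()
  budget <- problem$k +
    if (problem$forced_exempt) length(problem$forced) else 0L
  cons[[length(cons) + 1L]] <- lin_constraint(
    stats::setNames(rep(1, n), vv), "<=", budget, name = "budget")
  for (s in seq_len(nspl)) {
    mem <- sys$splits[s, ]
    for (side in c(0, 1)) {
      side_v <- vv[mem == side]
      cons[[length(cons) + 1L]] <- lin_constraint(
        stats::setNames(c(1, rep(-1, length(side_v))),
                        c(yv[s], side_v)), "<=", 0)
    }
  }
  if (!is.null(problem$web)) {
    web <- problem$web
    W <- if (!is.null(problem$d)) diet_matrix(web) else NULL
    for (j in setdiff(web$taxa, web$basal)) {
      prey_v <- vv[web$prey[[j]]]
      if (is.null(problem$d)) {
        cons[[length(cons) + 1L]] <- lin_constraint(
          stats::setNames(c(1, rep(-1, length(prey_v))),
                          c(vv[[j]], prey_v)), "<=", 0,
          name = paste0("viable_", j))
      } else {
        # scaled by 100/d so coefficients are O(1) in units of the
        # threshold and the solver's feasibility tolerance cannot blur
        # arbitrarily small d (the d -> 0+ reduction to plain viability
        # then holds exactly)
        need <- max(problem$d / 100 - problem$base_credit, 0)
        sc <- if (need > 0) 1 / need else 1
        cons[[length(cons) + 1L]] <- lin_constraint(
          stats::setNames(c(sc * W[j, web$prey[[j]]], -sc * need),
                          c(prey_v, vv[[j]])), ">=", 0,
          name = paste0("diet_", j))
      }
    }
  }
  for (t in problem$forced) {
    cons[[length(cons) + 1L]] <- lin_constraint(
      stats::setNames(1, vv[[t]]), "==", 1, name = paste0("forced_", t))
  }
  model <- ilp_model("max", stats::setNames(sys$weights, yv), cons,
                     vars = c(unname(vv), yv))
  attr(model, "var_map") <- list(v = vv, y = yv)
  model
}

infeasibility_certificate <- function(problem) {
  web <- problem$web
  if (is.null(web)) return("budget smaller than the forced set")
  msgs <- character(0)
  for (j in setdiff(problem$forced, web$basal)) {
    if (is.null(problem$d)) {
      msgs <- c(msgs, paste0("forced predator ", j, " needs one of its prey (",
                             paste(web$prey[[j]], collapse = ", "),
                             ") selected"))
    } else {
      tot <- sum(web$edges$proportion[web$edges$predator == j])
      if (tot + problem$base_credit < problem$d / 100 - 1e-9) {
        msgs <- c(msgs, paste0("predator ", j, " has only ",
                               round(100 * tot, 2),
                               "% of its diet in the web: unselectable at d = ",
                               problem$d, "%"))
      }
    }
  }
  if (length(msgs) == 0L) msgs <- "viability constraints unsatisfiable within k"
  paste(msgs, collapse = "; ")
}

#' Solve (d%-)viable taxon selection under SD
#'
#' Builds and exactly solves the taxon-selection ILP, then independently
#' re-checks the returned set with the plain predicates [is_viable()] /
#' [is_d_viable()] and recomputes its SD from the split system (not from
#' the solver's split variables).
#'
#' @param problem A `taxon_problem`.
#' @param time_limit Solver time limit (seconds).
#' @param lexicographic Deterministic tie-break; see [solve_ilp_lex()].
#' @param denominator Denominator convention for the reported relative SD;
#'   see [relative_sd()].
#' @return An object of class `taxon_solution` with the selected taxa, SD,
#'   relative SD and per-predator viability diagnostics; on infeasibility,
#'   status `"infeasible"` plus a certificate naming unsupportable
#'   predators.
#' @export
solve_taxon <- function(problem, time_limit = 60, lexicographic = FALSE,
                        denominator = c("all", "nontrivial")) {
  denominator <- match.arg(denominator)
  model <- build_taxon_model(problem)
  res <- if (lexicographic) {
    solve_ilp_lex(model, over = unname(attr(model, "var_map")$v),
                  time_limit = time_limit)
  } else {
    solve_ilp(model, time_limit = time_limit)
  }
  if (!identical(res$status, "optimal")) {
    return(structure(
      list(status = res$status, problem = problem,
           diagnostics = infeasibility_certificate(problem)),
      class = "taxon_solution"
    ))
  }
  vv <- attr(model, "var_map")$v
  selected <- names(vv)[res$assignment[unname(vv)] > 0.5]
  web <- problem$web
  viable <- if (is.null(web)) TRUE
  else if (is.null(problem$d)) is_viable(web, selected)
  else is_d_viable(web, selected, problem$d,
                   base_credit = problem$base_credit)
  if (!viable) {
    stop("internal error: solver returned a set failing the independent ",
         "viability predicate", call. = FALSE)
  }
  sdv <- sd_score(problem$system, selected)
  if (abs(sdv - res$objective) > 1e-6 * max(1, abs(sdv))) {
    stop("internal error: solver objective differs from recomputed SD",
         call. = FALSE)
  }
  diagnostics <- NULL
  if (!is.null(web)) {
    preds <- setdiff(selected, web$basal)
    diagnostics <- tibble::tibble(
      predator = preds,
      prey_selected = vapply(preds, function(j) {
        length(intersect(web$prey[[j]], selected))
      }, integer(1)),
      delta = if (web$has_diets) vapply(preds, function(j) {
        diet_score(web, j, selected, base_credit = problem$base_credit)
      }, numeric(1)) else NA_real_
    )
  }
  structure(
    list(status = "optimal", taxa = sort(selected), sd = sdv,
         sd_total = total_weight(problem$system),
         relative_sd = relative_sd(problem$system, selected,
                                   denominator = denominator),
         k = problem$k, d = problem$d, forced = problem$forced,
         diagnostics = diagnostics, problem = problem),
    class = "taxon_solution"
  )
}

#' @export
print.taxon_solution <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    cat("Taxon selection:", x$status, "\n")
    if (!is.null(x$diagnostics)) cat(" ", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat("Taxon selection (k = ", x$k,
      if (!is.null(x$d)) paste0(", d = ", x$d, "%") else "", "): ",
      length(x$taxa), " taxa, SD ", format(x$sd), " (",
      sprintf("%.2f", x$relative_sd), "% of total)\n", sep = "")
  invisible(x)
}

#' Diversity cost of ignoring the food web
#'
#' Solves the selection with and without the (d%-)viability constraints and
#' reports the SD difference together with the predators left without
#' support in the unconstrained optimum — the taxa whose viability the
#' constrained solution "repairs".
#'
#' @param problem A `taxon_problem` with a food web.
#' @param time_limit Solver time limit (seconds).
#' @return List with `constrained` and `unconstrained` (`taxon_solution`s),
#'   `sd_gap` (unconstrained minus constrained SD), `relative_sd_gap`
#'   (percentage points) and `unsupported` (predators without prey, or
#'   below d% diet, in the unconstrained optimum).
#' @export
unconstrained_gap <- function(problem, time_limit = 60) {
  stopifnot(inherits(problem, "taxon_problem"), !is.null(problem$web))
  free <- taxon_problem(problem$system, web = NULL, k = problem$k,
                        forced = problem$forced,
                        forced_exempt = problem$forced_exempt)
  sol_free <- solve_taxon(free, time_limit = time_limit)
  sol_con <- solve_taxon(problem, time_limit = time_limit)
  unsupported <- character(0)
  if (identical(sol_free$status, "optimal")) {
    web <- problem$web
    preds <- setdiff(sol_free$taxa, web$basal)
    unsupported <- if (is.null(problem$d)) {
      preds[vapply(preds, function(j) {
        length(intersect(web$prey[[j]], sol_free$taxa)) == 0L
      }, logical(1))]
    } else {
      preds[vapply(preds, function(j) {
        diet_score(web, j, sol_free$taxa,
                   base_credit = problem$base_credit) <
          problem$d / 100 - 1e-9
      }, logical(1))]
    }
  }
  sd_gap <- if (identical(sol_free$status, "optimal") &&
                identical(sol_con$status, "optimal")) {
    sol_free$sd - sol_con$sd
  } else NA_real_
  list(
    constrained = sol_con, unconstrained = sol_free, sd_gap = sd_gap,
    relative_sd_gap = if (is.na(sd_gap)) NA_real_ else
      100 * sd_gap / max(total_weight(problem$system), .Machine$double.eps),
    unsupported = unsupported
  )
}
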