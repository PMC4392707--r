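#' Build the ILP for spatial reserve selection under an SD target
#'
#' Formulates: minimize total area cost plus beta times the exterior fence
#' length of the selected reserve, subject to preserving at least p% of the
#' total split diversity. Variables: x_i per area; z_ij per adjacent pair
#' (b_ij > 0), linearizing the quadratic shared-boundary discount with
#' z_ij <= x_i and z_ij <= x_j (the lower bound z_ij >= x_i + x_j - 1 is
#' redundant because z_ij carries a negative cost in a minimization, and is
#' only emitted under `strict_z`); y_sigma per split, bounded above by the
#' number of selected areas covering each side of the split, so y_sigma = 1
#' only if the split separates the covered taxa. The SD constraint is
#' sum lambda_sigma y_sigma >= (p/100) sum lambda_sigma.
#'
#' @param land A `landscape`.
#' @param system A `split_system`; every system taxon must appear among the
#'   landscape's taxa.
#' @param p Percentage of total SD to preserve, in \[0, 100\].
#' @param scaled_integer Integer-scaled split weights and threshold
#'   (default TRUE); see [sd_threshold()].
#' @param strict_z Also emit the redundant lower-bound constraints on z.
#' @return An `ilp_model` with attributes `var_map` describing the
#'   area/pair/split behind each variable.
#' @export
build_reserve_model <- function(land, system, p, scaled_integer = TRUE,
                                strict_z = FALSE) {
  stopifnot(inherits(land, "landscape"), inherits(system, "split_system"),
            p >= 0, p <= 100)
  missing_tx <- setdiff(system$taxa, land$taxa)
  if (length(missing_tx)) {
    stop("system taxa absent from the landscape's presence matrix: ",
         paste(missing_tx, collapse = ", "), call. = FALSE)
  }
  m <- length(land$areas)
  xv <- paste0("x_", seq_len(m))
  obj <- stats::setNames(land$cost + land$beta * diag(land$B), xv)
  cons <- list()
  zv <- character(0)
  if (land$beta != 0) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (land$B[i, j] > 0) {
          z <- paste0("z_", i, "_", j)
          zv <- c(zv, z)
          obj[z] <- -2 * land$beta * land$B[i, j]
          cons[[length(cons) + 1L]] <- lin_constraint(
            stats::setNames(c(1, -1), c(z, xv[i])), "<=", 0)
          cons[[length(cons) + 1L]] <- lin_constraint(
            stats::setNames(c(1, -1), c(z, xv[j])), "<=", 0)
          if (strict_z) {
            cons[[length(cons) + 1L]] <- lin_constraint(
              stats::setNames(c(-1, 1, 1), c(z, xv[i], xv[j])), "<=", 1)
          }
        }
      }
    }
  }
  th <- sd_threshold(system, p, scaled_integer)
  nspl <- n_splits(system)
  yv <- if (nspl) paste0("y_", seq_len(nspl)) else character(0)
  tx_col <- match(system$taxa, land$taxa)
  for (s in seq_len(nspl)) {
    mem <- system$splits[s, ]
    for (side in c(0, 1)) {
      side_taxa <- tx_col[mem == side]
      cover <- which(rowSums(land$R[, side_taxa, drop = FALSE]) > 0)
      if (length(cover) == 0L) {
        message("split ", s, " has a side covered by no area; it can ",
                "never contribute to the target")
      }
      cons[[length(cons) + 1L]] <- lin_constraint(
        stats::setNames(c(1, rep(-1, length(cover))),
                        c(yv[s], xv[cover])), "<=", 0)
    }
  }
  if (nspl) {
    cons[[length(cons) + 1L]] <- lin_constraint(
      stats::setNames(th$weights, yv), ">=", th$threshold, name = "sd_target")
  }
  model <- ilp_model("min", obj, cons, vars = c(xv, zv, yv))
  attr(model, "var_map") <- list(x = stats::setNames(xv, land$areas),
                                 y = yv, z = zv)
  attr(model, "threshold") <- th
  model
}

new_reserve_solution <- function(status, land, system, p, selected = NULL,
                                 diagnostics = NULL) {
  if (!identical(status, "optimal")) {
    return(structure(list(status = status, p = p, beta = land$beta,
                          diagnostics = diagnostics),
                     class = "reserve_solution"))
  }
  cov <- covered_taxa(land, selected)
  sdv <- sd_score(system, intersect(system$taxa, cov))
  tot <- total_weight(system)
  y <- vapply(seq_len(n_splits(system)), function(s) {
    as.numeric(separates(system$splits[s, ], intersect(system$taxa, cov),
                         taxa = system$taxa))
  }, numeric(1))
  ai <- match(selected, land$areas)
  area_table <- tibble::tibble(
    area = selected,
    cost = land$cost[ai],
    urban = land$urban[ai],
    n_taxa = as.integer(rowSums(land$R[ai, , drop = FALSE]))
  )
  structure(
    list(status = "optimal", areas = selected, covered_taxa = cov,
         area_table = area_table,
         cost = sum(land$cost[match(selected, land$areas)]),
         fence = fence_length(land, selected),
         objective = reserve_objective(land, selected),
         sd = sdv, sd_total = tot,
         sd_pct = if (tot > 0) 100 * sdv / tot else 0,
         y = y, p = p, beta = land$beta, diagnostics = diagnostics),
    class = "reserve_solution"
  )
}

#' @export
print.reserve_solution <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    cat("Reserve selection:", x$status, "\n")
    if (!is.null(x$diagnostics)) cat(" ", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat("Reserve selection (p = ", x$p, "%, beta = ", x$beta, "): ",
      length(x$areas), " areas, objective ", format(x$objective),
      " (cost ", format(x$cost), " + fence ", format(x$fence), ")\n",
      "SD attained: ", format(x$sd), " (", sprintf("%.2f", x$sd_pct),
      "% of total)\n", sep = "")
  invisible(x)
}

#' Solve spatial reserve selection under an SD target
#'
#' Builds and exactly solves the reserve-selection ILP, then independently
#' recomputes the SD of the covered taxa from the presence matrix (not from
#' the solver's split variables) and asserts the target is met. The
#' reported per-split indicators are likewise recomputed from coverage.
#'
#' @inheritParams build_reserve_model
#' @param time_limit Solver time limit (seconds).
#' @param lexicographic Deterministically pick the lexicographically
#'   smallest optimal area set (slower; objective unchanged).
#' @return A `reserve_solution`; on infeasibility, status
#'   `"infeasible"` with diagnostics instead of an error.
#' @export
solve_reserve <- function(land, system, p, scaled_integer = TRUE,
                          strict_z = FALSE, time_limit = 60,
                          lexicographic = FALSE) {
  tx <- match(system$taxa, land$taxa)
  if (anyNA(tx)) {
    stop("system taxa absent from the landscape's presence matrix: ",
         paste(system$taxa[is.na(tx)], collapse = ", "), call. = FALSE)
  }
  coverable <- colSums(land$R[, tx, drop = FALSE]) > 0
  if (p == 100 && any(!coverable)) {
    # a positive-weight split with one side made only of uncoverable taxa
    # can never separate the covered taxa, so p = 100% is unattainable
    blocked <- vapply(seq_len(n_splits(system)), function(s) {
      if (system$weights[s] <= 0) return(FALSE)
      mem <- system$splits[s, ]
      !any(coverable[mem == 1]) || !any(coverable[mem == 0])
    }, logical(1))
    if (any(blocked)) {
      return(new_reserve_solution(
        "infeasible", land, system, p,
        diagnostics = paste0("taxa occurring in no area make p = 100% ",
                             "unattainable: ",
                             paste(system$taxa[!coverable], collapse = ", "))))
    }
  }
  model <- build_reserve_model(land, system, p, scaled_integer, strict_z)
  res <- if (lexicographic) {
    solve_ilp_lex(model, over = attr(model, "var_map")$x,
                  time_limit = time_limit)
  } else {
    solve_ilp(model, time_limit = time_limit)
  }
  if (!identical(res$status, "optimal")) {
    return(new_reserve_solution(res$status, land, system, p,
                                diagnostics = "no area subset attains the SD target"))
  }
  xv <- attr(model, "var_map")$x
  selected <- names(xv)[res$assignment[xv] > 0.5]
  sol <- new_reserve_solution("optimal", land, system, p, selected)
  th <- attr(model, "threshold")
  attained <- sd_of_subset_weighted(
    system, th$weights,
    match(intersect(system$taxa, sol$covered_taxa), system$taxa))
  if (attained < th$threshold - 1e-6 * max(1, th$threshold)) {
    stop("internal error: solver selection misses the SD target on ",
         "independent recomputation", call. = FALSE)
  }
  sol
}

#' Minimum representation problem
#'
#' The classical cheapest-coverage problem: minimize total cost such that
#' every taxon is present in at least one selected area. Equivalent to
#' reserve selection at p = 100% with beta = 0 on a split system containing
#' all trivial splits.
#'
#' @param land A `landscape`.
#' @param time_limit Solver time limit (seconds).
#' @return A `reserve_solution` (SD fields refer to a unit-weight
#'   trivial-split system over the landscape's taxa).
#' @export
minimum_representation <- function(land, time_limit = 60) {
  uncovered <- land$taxa[colSums(land$R) == 0]
  if (length(uncovered)) {
    return(new_reserve_solution(
      "infeasible", land, list(), 100,
      diagnostics = paste0("taxa occurring in no area: ",
                           paste(uncovered, collapse = ", "))))
  }
  m <- length(land$areas)
  xv <- paste0("x_", seq_len(m))
  cons <- lapply(seq_along(land$taxa), function(j) {
    cover <- which(land$R[, j] > 0)
    lin_constraint(stats::setNames(rep(1, length(cover)), xv[cover]),
                   ">=", 1, name = paste0("cover_", land$taxa[j]))
  })
  model <- ilp_model("min", stats::setNames(land$cost, xv), cons, vars = xv)
  res <- solve_ilp(model, time_limit = time_limit)
  if (!identical(res$status, "optimal")) {
    return(new_reserve_solution("infeasible", land, list(), 100,
                                diagnostics = "set cover infeasible"))
  }
  selected <- land$areas[res$assignment[xv] > 0.5]
  triv <- split_system(land$taxa, diag(length(land$taxa)),
                       rep(1, length(land$taxa)))
  land0 <- land
  land0$beta <- 0
  new_reserve_solution("optimal", land0, triv, 100, selected)
}

#' Sweep the urban/rural cost ratio
#'
#' Models increasing economic pressure on urban planning units: at ratio
#' rho, every urban area's cost is its base cost times rho while rural
#' costs stay fixed, and the reserve-selection ILP is re-solved. Because
#' the optimum is a discrete set, the minimal cost is piecewise linear in
#' rho; consecutive ratios with identical optimal sets are merged into
#' intervals, each reported with its exact cost line: intercept = rural
#' cost of the set + beta * fence, slope = summed base urban cost of the
#' set (zero once no urban area is selected).
#'
#' @inheritParams solve_reserve
#' @param ratios Ascending grid of urban/rural cost ratios (>= 1 value).
#' @param lexicographic Resolve ties at every ratio by the lexicographically
#'   smallest optimal set (slower: solves sequentially instead of in one
#'   batched call).
#' @return A `cost_ratio_sweep` object; its `intervals` tibble has one row
#'   per optimal set with `ratio_min`, `ratio_max`, `areas` (list-column),
#'   `n_areas`, `n_urban`, `intercept` and `slope`.
#' @export
cost_ratio_sweep <- function(land, system, p, ratios, scaled_integer = TRUE,
                             time_limit = 60, lexicographic = FALSE) {
  ratios <- as.numeric(ratios)
  stopifnot(length(ratios) >= 1L, !is.unsorted(ratios))
  sets <- vector("list", length(ratios))
  lands <- lapply(ratios, function(r) {
    li <- land
    li$cost <- ifelse(land$urban, land$cost * r, land$cost)
    li
  })
  if (lexicographic) {
    for (i in seq_along(ratios)) {
      sol <- solve_reserve(lands[[i]], system, p,
                           scaled_integer = scaled_integer,
                           time_limit = time_limit, lexicographic = TRUE)
      if (!identical(sol$status, "optimal")) {
        stop("sweep infeasible at ratio ", ratios[i], call. = FALSE)
      }
      sets[[i]] <- sort(sol$areas)
    }
  } else {
    models <- lapply(lands, function(li) {
      build_reserve_model(li, system, p, scaled_integer = scaled_integer)
    })
    res <- solve_ilp_batch(models, time_limit = time_limit)
    for (i in seq_along(ratios)) {
      if (!identical(res[[i]]$status, "optimal")) {
        stop("sweep infeasible at ratio ", ratios[i], call. = FALSE)
      }
      xv <- attr(models[[i]], "var_map")$x
      sets[[i]] <- sort(names(xv)[res[[i]]$assignment[xv] > 0.5])
    }
  }
  key <- vapply(sets, paste, "", collapse = "|")
  run <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  rows <- lapply(unique(run), function(r) {
    idx <- which(run == r)
    set <- sets[[idx[1L]]]
    ai <- match(set, land$areas)
    urb <- land$urban[ai]
    tibble::tibble(
      ratio_min = ratios[idx[1L]],
      ratio_max = ratios[idx[length(idx)]],
      areas = list(set),
      n_areas = length(set),
      n_urban = sum(urb),
      intercept = sum(land$cost[ai][!urb]) +
        land$beta * fence_length(land, set),
      slope = sum(land$cost[ai][urb])
    )
  })
  structure(
    list(intervals = dplyr::bind_rows(rows), ratios = ratios, p = p,
         beta = land$beta),
    class = "cost_ratio_sweep"
  )
}

#' @export
print.cost_ratio_sweep <- function(x, ...) {
  cat("Cost-ratio sweep (p = ", x$p, "%): ", nrow(x$intervals),
      " optimal set(s) over ratios [", min(x$ratios), ", ", max(x$ratios),
      "]\n", sep = "")
  print(x$intervals)
  invisible(x)
}

#' @export
tidy.cost_ratio_sweep <- function(x, ...) x$intervals

cost_line <- function(line) {
  if (inherits(line, "tbl_df") || is.data.frame(line)) {
    stopifnot(nrow(line) == 1L)
    c(intercept = line$intercept[[1L]], slope = line$slope[[1L]])
  } else {
    stopifnot(all(c("intercept", "slope") %in% names(line)))
    c(intercept = as.numeric(line[["intercept"]]),
      slope = as.numeric(line[["slope"]]))
  }
}

#' Break-even ratio of accumulated conservation costs
#'
#' Given two optimal sets' cost lines (cost = intercept + slope * rho) and
#' a trajectory of ratios increasing over time, accumulates each set's cost
#' over the trajectory and reports the smallest ratio at which set A's
#' cumulative cost exceeds set B's — the point past which committing to the
#' initially more expensive but flatter-sloped set B pays off. The default
#' discrete mode sums costs step by step over the given grid; the analytic
#' mode solves the accumulated-cost equality in closed form (the positive
#' root of a quadratic) assuming a uniform grid, and returns the grid point
#' at or above that root.
#'
#' @param line_a,line_b Cost lines: one-row tibbles from
#'   [cost_ratio_sweep()] intervals, or vectors with `intercept`/`slope`.
#' @param ratios Ascending ratio trajectory starting at the present ratio.
#' @param mode `"discrete"` or `"analytic"`.
#' @return List with `crossover` (ratio, or NA if the curves never cross
#'   within the trajectory), `mode` and for the discrete mode a tibble
#'   `details` of cumulative costs.
#' @export
accumulated_cost_crossover <- function(line_a, line_b, ratios,
                                       mode = c("discrete", "analytic")) {
  mode <- match.arg(mode)
  a <- cost_line(line_a)
  b <- cost_line(line_b)
  ratios <- as.numeric(ratios)
  stopifnot(length(ratios) >= 1L, !is.unsorted(ratios))
  cost_a <- a["intercept"] + a["slope"] * ratios
  cost_b <- b["intercept"] + b["slope"] * ratios
  if (mode == "discrete") {
    cum_a <- cumsum(cost_a)
    cum_b <- cumsum(cost_b)
    over <- which(cum_a > cum_b + 1e-9)
    details <- tibble::tibble(ratio = ratios, cum_a = cum_a, cum_b = cum_b)
    if (length(over) == 0L) {
      return(list(crossover = NA_real_, mode = mode, details = details))
    }
    return(list(crossover = ratios[over[1L]], mode = mode,
                details = details))
  }
  # analytic: uniform grid rho_t = r0 + h (t - 1); cumulative difference
  # D(T) = di * T + ds * sum_t rho_t = T * (di + ds * r0) + ds * h * T(T-1)/2
  # with di = iA - iB, ds = sA - sB; smallest T > 0 with D(T) > 0.
  di <- a["intercept"] - b["intercept"]
  ds <- a["slope"] - b["slope"]
  r0 <- ratios[1L]
  h <- if (length(ratios) > 1L) ratios[2L] - ratios[1L] else 0
  if (h > 0 && max(abs(diff(ratios) - h)) > 1e-9) {
    stop("analytic mode requires a uniform ratio grid", call. = FALSE)
  }
  if (ds == 0 || h == 0) {
    # cumulative difference is linear in T
    slope_T <- di + ds * r0
    if (slope_T <= 0) return(list(crossover = NA_real_, mode = mode))
    return(list(crossover = ratios[1L], mode = mode))
  }
  # ds*h/2 * T^2 + (di + ds*r0 - ds*h/2) * T > 0  =>  T > T*
  qa <- ds * h / 2
  qb <- di + ds * r0 - ds * h / 2
  t_star <- -qb / qa  # nonzero root of qa*T^2 + qb*T = 0
  if (qa > 0) {
    t_first <- max(1, floor(t_star) + 1)
  } else {
    # concave difference: positive only below the root
    if (t_star <= 1) return(list(crossover = NA_real_, mode = mode))
    t_first <- 1
  }
  if (t_first > length(ratios)) {
    return(list(crossover = NA_real_, mode = mode))
  }
  list(crossover = r0 + h * (t_first - 1), mode = mode)
}
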