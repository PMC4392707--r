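#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reserve solution
#'
#' @param x A `reserve_solution`.
#' @param ... Unused.
#' @return A tibble with one row per selected area: `area`, `cost`,
#'   `urban` and `n_taxa` (taxa present in the area).
#' @export
tidy.reserve_solution <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    return(tibble::tibble(area = character(0), cost = numeric(0),
                          urban = logical(0), n_taxa = integer(0)))
  }
  x$area_table
}

#' One-row summary of a reserve solution
#'
#' @param x A `reserve_solution`.
#' @param ... Unused.
#' @export
glance.reserve_solution <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    return(tibble::tibble(status = x$status))
  }
  tibble::tibble(
    status = x$status, n_areas = length(x$areas), cost = x$cost,
    fence = x$fence, objective = x$objective, sd = x$sd,
    sd_pct = x$sd_pct, n_taxa = length(x$covered_taxa), p = x$p,
    beta = x$beta
  )
}

#' Tidy a taxon solution
#'
#' @param x A `taxon_solution`.
#' @param ... Unused.
#' @return A tibble with one row per selected taxon, joined with the
#'   per-predator viability diagnostics where available (`prey_selected`,
#'   `delta`; NA for basal taxa).
#' @export
tidy.taxon_solution <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    return(tibble::tibble(taxon = character(0)))
  }
  out <- tibble::tibble(taxon = x$taxa,
                        forced = x$taxa %in% x$forced)
  if (!is.null(x$diagnostics) && nrow(x$diagnostics)) {
    out <- dplyr::left_join(out, x$diagnostics,
                            by = c(taxon = "predator"))
  }
  out
}

#' One-row summary of a taxon solution
#'
#' @param x A `taxon_solution`.
#' @param ... Unused.
#' @export
glance.taxon_solution <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    return(tibble::tibble(status = x$status))
  }
  tibble::tibble(
    status = x$status, n_taxa = length(x$taxa), sd = x$sd,
    sd_total = x$sd_total, relative_sd = x$relative_sd, k = x$k,
    d = if (is.null(x$d)) NA_real_ else x$d
  )
}

#' Plot the piecewise-linear cost curve of a ratio sweep
#'
#' Draws the minimal conservation cost as a function of the urban/rural
#' cost ratio: one line segment per optimal set, with points marking the
#' change-overs between sets (steeper early segments select urban areas;
#' the terminal flat segment contains none).
#'
#' @param object A `cost_ratio_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cost_ratio_sweep <- function(object, ...) {
  iv <- object$intervals
  seg <- dplyr::mutate(
    iv,
    cost_min = .data$intercept + .data$slope * .data$ratio_min,
    cost_max = .data$intercept + .data$slope * .data$ratio_max,
    set = factor(seq_len(nrow(iv)))
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ratio_min, xend = .data$ratio_max,
      y = .data$cost_min, yend = .data$cost_max,
      colour = .data$set)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$ratio_min,
                                     y = .data$cost_min)) +
    ggplot2::labs(x = "urban/rural cost ratio", y = "minimal cost",
                  colour = "optimal set",
                  title = paste0("Reserve cost under economic pressure (p = ",
                                 object$p, "%)")) +
    ggplot2::theme_minimal()
}

#' Plot per-predator diet diagnostics of a taxon solution
#'
#' Bar chart of the conserved diet fraction delta(s_j | S) for every
#' selected predator, with the d% threshold marked when the problem used
#' one.
#'
#' @param object A `taxon_solution` solved over a weighted food web.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taxon_solution <- function(object, ...) {
  if (!identical(object$status, "optimal") || is.null(object$diagnostics) ||
      all(is.na(object$diagnostics$delta))) {
    stop("nothing to plot: need an optimal solution with diet diagnostics",
         call. = FALSE)
  }
  d <- object$diagnostics
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$predator, .data$delta), y = .data$delta)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "conserved diet fraction δ(s|S)") +
    ggplot2::theme_minimal()
  if (!is.null(object$d)) {
    p <- p + ggplot2::geom_hline(yintercept = object$d / 100,
                                 linetype = "dashed")
  }
  p
}

#' @importFrom rlang .data
NULL
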