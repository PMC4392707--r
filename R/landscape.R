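#' Construct a reserve-selection landscape
#'
#' Bundles the spatial instance of the reserve-selection problem: which
#' taxa occur in which planning units, what each unit costs, the boundary
#' geometry used for the fencing term, and the boundary-cost rate beta.
#'
#' @param presence An m x n binary matrix (areas x taxa) with area ids as
#'   row names and taxon labels as column names, or a data frame whose
#'   first column holds area ids and remaining columns taxa.
#' @param cost Numeric vector of per-area conservation costs (cost units),
#'   in area order or named by area id.
#' @param boundary Symmetric m x m matrix (length units): diagonal entries
#'   are area perimeters, off-diagonal entries shared boundary lengths
#'   (0 for non-adjacent pairs). Defaults to all-zero (no fencing term).
#' @param beta Conservation cost per unit boundary length (default 0).
#' @param urban Logical vector flagging urban areas (default all rural);
#'   used by [cost_ratio_sweep()].
#' @return An object of class `landscape` with fields `areas`, `taxa`, `R`,
#'   `cost`, `B`, `beta`, `urban`.
#' @export
landscape <- function(presence, cost, boundary = NULL, beta = 0,
                      urban = NULL) {
  if (is.data.frame(presence)) {
    ids <- as.character(presence[[1L]])
    R <- as.matrix(presence[, -1L, drop = FALSE])
    rownames(R) <- ids
  } else {
    R <- as.matrix(presence)
  }
  storage.mode(R) <- "numeric"
  if (is.null(rownames(R)) || is.null(colnames(R))) {
    stop("presence matrix needs area ids as row names and taxon labels as ",
         "column names", call. = FALSE)
  }
  if (anyNA(R) || !all(R %in% c(0, 1))) {
    stop("presence entries must be 0/1", call. = FALSE)
  }
  areas <- rownames(R)
  m <- length(areas)
  if (!is.null(names(cost))) cost <- cost[areas]
  cost <- as.numeric(cost)
  if (length(cost) != m || anyNA(cost) || any(cost < 0)) {
    stop("`cost` must give one non-negative cost per area", call. = FALSE)
  }
  if (is.null(boundary)) boundary <- matrix(0, m, m,
                                            dimnames = list(areas, areas))
  B <- as.matrix(boundary)
  if (!is.null(rownames(B))) B <- B[areas, areas, drop = FALSE]
  storage.mode(B) <- "numeric"
  if (nrow(B) != m || ncol(B) != m || anyNA(B) || any(B < 0)) {
    stop("`boundary` must be a non-negative m x m matrix", call. = FALSE)
  }
  if (max(abs(B - t(B))) > 1e-9) {
    stop("`boundary` must be symmetric", call. = FALSE)
  }
  shared <- rowSums(B) - diag(B)
  if (any(diag(B) < shared - 1e-9)) {
    warning("boundary geometry inconsistent: some perimeter b_ii is ",
            "smaller than the summed shared boundaries of area i",
            call. = FALSE)
  }
  if (is.null(urban)) urban <- rep(FALSE, m)
  urban <- as.logical(urban)
  if (length(urban) != m || anyNA(urban)) {
    stop("`urban` must be one flag per area", call. = FALSE)
  }
  structure(
    list(areas = areas, taxa = colnames(R), R = R, cost = cost, B = B,
         beta = as.numeric(beta), urban = urban),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("Landscape:", length(x$areas), "areas x", length(x$taxa), "taxa,",
      "beta =", format(x$beta),
      if (any(x$urban)) paste0("(", sum(x$urban), " urban)") else "", "\n")
  invisible(x)
}

#' Taxa covered by a set of areas
#'
#' @param land A `landscape`.
#' @param selected Area ids or indices.
#' @return Character vector of taxa present in at least one selected area.
#' @export
covered_taxa <- function(land, selected) {
  idx <- resolve_subset(land$areas, selected)
  if (length(idx) == 0L) return(character(0))
  land$taxa[colSums(land$R[idx, , drop = FALSE]) > 0]
}

#' Fence length of a reserve
#'
#' Total exterior boundary of the selected areas: the summed perimeters
#' minus twice every shared boundary between co-selected areas (shared
#' boundaries are internal and need no fencing).
#'
#' @param land A `landscape`.
#' @param selected Area ids or indices.
#' @export
fence_length <- function(land, selected) {
  idx <- resolve_subset(land$areas, selected)
  if (length(idx) == 0L) return(0)
  Bs <- land$B[idx, idx, drop = FALSE]
  sum(diag(Bs)) - (sum(Bs) - sum(diag(Bs)))
}

reserve_objective <- function(land, selected) {
  idx <- resolve_subset(land$areas, selected)
  sum(land$cost[idx]) + land$beta * fence_length(land, idx)
}
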