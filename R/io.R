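# Readers and writers for the interchange formats: Newick tree files,
# SplitsTree-style NEXUS SPLITS blocks, presence/cost/boundary CSV tables,
# food-web TSV edge lists and a key-value result file. Readers reject
# malformed input rather than silently coercing it.

strip_label_quotes <- function(x) {
  gsub("^'(.*)'$", "\\1", x)
}

#' Read one or more Newick trees
#'
#' Parses every semicolon-terminated tree in the file. Single-quoted labels
#' are honored (quotes stripped). Trees without branch lengths are accepted
#' (lengths default to 0 at split extraction, with a warning there).
#'
#' @param path Path to a Newick file.
#' @return A list of `ape::phylo` trees (class `multiPhylo`).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl(";", txt)) {
    stop("no Newick tree found in ", path, " (missing ';')", call. = FALSE)
  }
  trees <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) {
      stop("malformed Newick in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(trees)) {
    # locate the offending chunk for a useful position report
    chunks <- strsplit(txt, ";", fixed = TRUE)[[1L]]
    offset <- 0L
    for (i in seq_along(chunks)) {
      if (nzchar(trimws(chunks[i]))) {
        one <- tryCatch(ape::read.tree(text = paste0(chunks[i], ";")),
                        error = function(e) NULL)
        if (is.null(one)) {
          stop("malformed Newick in ", path, ": tree ", i,
               " (near character ", offset + 1L, ")", call. = FALSE)
        }
      }
      offset <- offset + nchar(chunks[i]) + 1L
    }
    stop("malformed Newick in ", path, call. = FALSE)
  }
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                  class = "multiPhylo")
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- strip_label_quotes(tr$tip.label)
    if (anyDuplicated(tr$tip.label)) {
      stop("duplicate leaf labels in ", path, call. = FALSE)
    }
    tr
  })
  message("read ", length(trees), " tree(s) from ", path, " over ",
          length(unique(unlist(lapply(trees, `[[`, "tip.label")))),
          " taxa")
  structure(trees, class = "multiPhylo")
}

nexus_tokens <- function(line) {
  # tokenize respecting single-quoted labels
  regmatches(line, gregexpr("'[^']*'|[^[:space:],;]+", line))[[1L]]
}

#' Read a split system from a NEXUS SPLITS block
#'
#' Parses the SplitsTree dialect: a TAXA block with TAXLABELS and a SPLITS
#' block whose MATRIX lists, per split, a weight followed by the 1-based
#' indices of the taxa on one side. Bracketed comments (including the
#' leading `[id, size=k]` labels SplitsTree writes) are ignored. A CYCLE
#' command is ignored with a warning; duplicate splits are merged by
#' summing weights, with a warning.
#'
#' @param path Path to a NEXUS file.
#' @return A `split_system`.
#' @export
read_splits_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  txt <- paste(raw, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    stop(path, " is not a NEXUS file", call. = FALSE)
  }
  txt <- gsub("\\[[^]]*\\]", " ", txt)  # strip bracketed comments
  grab_block <- function(name) {
    m <- regexpr(paste0("(?is)begin\\s+", name, "\\s*;.*?end\\s*;"), txt,
                 perl = TRUE)
    if (m == -1L) stop("NEXUS ", toupper(name), " block missing in ", path,
                       call. = FALSE)
    regmatches(txt, m)
  }
  tax_block <- grab_block("taxa")
  m <- regexpr("(?is)taxlabels(.*?);", tax_block, perl = TRUE)
  if (m == -1L) stop("TAXLABELS missing in TAXA block", call. = FALSE)
  lab_txt <- sub("(?is)^taxlabels", "", regmatches(tax_block, m), perl = TRUE)
  taxa <- strip_label_quotes(nexus_tokens(gsub(";", " ", lab_txt)))
  if (length(taxa) < 1L) stop("no taxa in TAXLABELS", call. = FALSE)

  spl_block <- grab_block("splits")
  if (grepl("(?i)cycle", spl_block, perl = TRUE)) {
    warning("CYCLE command in SPLITS block ignored", call. = FALSE)
  }
  m <- regexpr("(?is)matrix(.*?);", spl_block, perl = TRUE)
  if (m == -1L) stop("MATRIX missing in SPLITS block", call. = FALSE)
  mat_txt <- sub("(?is)^matrix", "", regmatches(spl_block, m), perl = TRUE)
  mat_txt <- sub(";\\s*$", "", mat_txt)
  rows <- strsplit(mat_txt, ",")[[1L]]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0L) stop("empty SPLITS matrix", call. = FALSE)
  mems <- list()
  weights <- numeric(0)
  for (r in seq_along(rows)) {
    tok <- nexus_tokens(rows[r])
    if (length(tok) < 2L) {
      stop("SPLITS matrix row ", r, " needs a weight and taxon indices",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) {
      stop("non-numeric entry in SPLITS matrix row ", r, call. = FALSE)
    }
    w <- vals[1L]
    idx <- vals[-1L]
    if (any(idx != round(idx)) || any(idx < 1) || any(idx > length(taxa))) {
      stop("split indices out of taxon range in SPLITS matrix row ", r,
           call. = FALSE)
    }
    mem <- integer(length(taxa))
    mem[as.integer(idx)] <- 1L
    mems[[r]] <- mem
    weights[r] <- w
  }
  split_system(taxa, mems, weights, warn_duplicates = TRUE)
}

#' Write a split system as a NEXUS SPLITS block
#'
#' Emits TAXA and SPLITS blocks in the SplitsTree dialect readable by
#' [read_splits_nexus()] (round-trip identity on canonical systems).
#'
#' @param system A `split_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splits_nexus <- function(system, path) {
  stopifnot(inherits(system, "split_system"))
  n <- length(system$taxa)
  quote_if <- function(x) {
    ifelse(grepl("[ \t'(),;:]", x), paste0("'", x, "'"), x)
  }
  lines <- c(
    "#NEXUS",
    "",
    "BEGIN TAXA;",
    paste0("DIMENSIONS NTAX=", n, ";"),
    "TAXLABELS",
    paste0("  [", seq_len(n), "] ", quote_if(system$taxa)),
    ";",
    "END;",
    "",
    "BEGIN SPLITS;",
    paste0("DIMENSIONS NTAX=", n, " NSPLITS=", n_splits(system), ";"),
    "FORMAT LABELS=NO WEIGHTS=YES;",
    "MATRIX"
  )
  for (s in seq_len(n_splits(system))) {
    idx <- which(system$splits[s, ] == 1)
    lines <- c(lines, paste0("  [", s, "]\t",
                             format(system$weights[s], digits = 15),
                             "\t", paste(idx, collapse = " "), ","))
  }
  lines <- c(lines, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a presence/absence table
#'
#' CSV with a header row; the first column holds area ids, the remaining
#' columns (named by taxon) hold 0/1 presence values.
#'
#' @param path Path to a CSV file.
#' @return A tibble suitable for [landscape()].
#' @export
read_presence_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) < 2L) stop("presence table needs an area column and at ",
                          "least one taxon column", call. = FALSE)
  vals <- unlist(df[, -1L])
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop("presence entries must be 0/1", call. = FALSE)
  }
  df[[1L]] <- as.character(df[[1L]])
  df
}

#' Read an area cost table
#'
#' CSV with columns `area`, `cost` and optional `urban` (0/1).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `area`, `cost`, `urban` (logical).
#' @export
read_costs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("area", "cost") %in% names(df))) {
    stop("cost table needs columns `area` and `cost`", call. = FALSE)
  }
  df$area <- as.character(df$area)
  df$cost <- as.numeric(df$cost)
  if (anyNA(df$cost) || any(df$cost < 0)) {
    stop("costs must be non-negative numbers", call. = FALSE)
  }
  df$urban <- if ("urban" %in% names(df)) {
    u <- df$urban
    if (anyNA(u) || !all(u %in% c(0, 1))) {
      stop("urban flags must be 0/1", call. = FALSE)
    }
    as.logical(u)
  } else FALSE
  df[c("area", "cost", "urban")]
}

#' Read a boundary-length matrix
#'
#' Square CSV matrix with area ids as header row and first column;
#' diagonal entries are perimeters, off-diagonal entries shared boundary
#' lengths.
#'
#' @param path Path to a CSV file.
#' @return A numeric matrix with area ids as dimnames.
#' @export
read_boundary_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(df[[1L]])
  B <- as.matrix(df[, -1L])
  if (nrow(B) != ncol(B) || !setequal(colnames(B), ids)) {
    stop("boundary matrix must be square with matching area ids in the ",
         "header and first column", call. = FALSE)
  }
  storage.mode(B) <- "numeric"
  if (anyNA(B)) stop("non-numeric boundary entries", call. = FALSE)
  rownames(B) <- ids
  B[ids, ids]
}

#' Read a food web edge list
#'
#' TSV with a header line and columns `predator`, `prey` and optionally
#' `proportion` (diet fraction of the prey in the predator's diet). Without
#' the proportion column the web is unweighted.
#'
#' @param path Path to a TSV file.
#' @param taxa Optional full taxon set (taxa absent from the edge list are
#'   basal).
#' @return A `food_web`.
#' @export
read_foodweb_tsv <- function(path, taxa = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("predator", "prey") %in% names(df))) {
    stop("food-web table needs header columns `predator` and `prey`",
         call. = FALSE)
  }
  food_web(df, taxa = taxa)
}

#' Write a food web edge list
#' @param web A `food_web`.
#' @param path Output path.
#' @export
write_foodweb_tsv <- function(web, path) {
  readr::write_tsv(web$edges, path)
  invisible(path)
}

#' Cross-file taxon-name preflight
#'
#' Taxon matching between input files is exact and case-sensitive; this
#' reports the names present in one source but not another before any
#' solve is attempted.
#'
#' @param ... Named character vectors of taxon labels, one per source.
#' @return A tibble with columns `name`, and one logical column per source;
#'   only names missing from at least one source are listed.
#' @export
check_names <- function(...) {
  sources <- list(...)
  stopifnot(length(sources) >= 2L, !is.null(names(sources)))
  all_names <- sort(unique(unlist(sources)))
  tab <- tibble::tibble(name = all_names)
  for (s in names(sources)) tab[[s]] <- all_names %in% sources[[s]]
  tab[rowSums(!as.matrix(tab[, -1L])) > 0, ]
}

#' Write a solution as a key-value result file
#'
#' Machine-readable `key: value` lines covering the selection, objective,
#' SD attained and run metadata (including the seed, for reproducibility).
#'
#' @param solution A `reserve_solution` or `taxon_solution`.
#' @param path Output path.
#' @param seed Seed to record (NA if none was used).
#' @return `path`, invisibly.
#' @export
write_result <- function(solution, path, seed = NA) {
  kv <- function(k, v) paste0(k, ": ", paste(v, collapse = ","))
  lines <- c(kv("status", solution$status), kv("seed", seed))
  if (inherits(solution, "reserve_solution") &&
      identical(solution$status, "optimal")) {
    lines <- c(lines,
               kv("selected_areas", solution$areas),
               kv("objective", format(solution$objective, digits = 15)),
               kv("cost", format(solution$cost, digits = 15)),
               kv("fence", format(solution$fence, digits = 15)),
               kv("sd", format(solution$sd, digits = 15)),
               kv("sd_pct", format(solution$sd_pct, digits = 15)),
               kv("covered_taxa", solution$covered_taxa))
  } else if (inherits(solution, "taxon_solution") &&
             identical(solution$status, "optimal")) {
    lines <- c(lines,
               kv("selected_taxa", solution$taxa),
               kv("sd", format(solution$sd, digits = 15)),
               kv("relative_sd_pct", format(solution$relative_sd,
                                            digits = 15)))
  } else if (!is.null(solution$diagnostics) &&
             is.character(solution$diagnostics)) {
    lines <- c(lines, kv("diagnostics", solution$diagnostics))
  }
  writeLines(lines, path)
  invisible(path)
}
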