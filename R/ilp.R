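#' Build a 0/1 integer linear program
#'
#' Solver-agnostic intermediate form: binary variables with string names, a
#' linear objective and linear constraints. Models are plain lists so they
#' can be serialized, exported in LP format or handed to the solver bridge.
#'
#' @param sense `"min"` or `"max"`.
#' @param objective Named numeric vector of objective coefficients;
#'   variables absent from it have coefficient 0.
#' @param constraints List of constraints created with [lin_constraint()].
#' @param vars Character vector of all variable names; defaults to the
#'   union of names in the objective and constraints.
#' @return An object of class `ilp_model`.
#' @export
ilp_model <- function(sense, objective, constraints = list(), vars = NULL) {
  sense <- match.arg(sense, c("min", "max"))
  if (length(objective) && is.null(names(objective))) {
    stop("objective coefficients must be named", call. = FALSE)
  }
  if (is.null(vars)) {
    vars <- unique(c(names(objective),
                     unlist(lapply(constraints, function(ct) names(ct$coefs)))))
  }
  vars <- as.character(vars)
  if (anyDuplicated(vars)) stop("duplicate variable names", call. = FALSE)
  coefs_ok <- all(is.finite(objective)) &&
    all(vapply(constraints, function(ct) {
      all(is.finite(ct$coefs)) && is.finite(ct$rhs)
    }, logical(1)))
  if (!coefs_ok) stop("non-finite coefficients in model", call. = FALSE)
  bad <- setdiff(
    unique(c(names(objective),
             unlist(lapply(constraints, function(ct) names(ct$coefs))))),
    vars
  )
  if (length(bad)) stop("constraints reference undeclared variables: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(sense = sense, objective = objective,
                 constraints = constraints, vars = vars),
            class = "ilp_model")
}

#' Linear constraint helper
#'
#' @param coefs Named numeric coefficients.
#' @param dir One of `"<="`, `">="`, `"=="`.
#' @param rhs Scalar right-hand side.
#' @param name Optional label used in diagnostics and LP export.
#' @export
lin_constraint <- function(coefs, dir, rhs, name = NULL) {
  if (!is.character(dir) || length(dir) != 1L ||
      !dir %in% c("<=", ">=", "==")) {
    stop("`dir` must be one of \"<=\", \">=\", \"==\"", call. = FALSE)
  }
  list(coefs = coefs, dir = dir, rhs = as.numeric(rhs), name = name)
}

#' @export
print.ilp_model <- function(x, ...) {
  cat("ILP (", x$sense, "): ", length(x$vars), " binary variables, ",
      length(x$constraints), " constraints\n", sep = "")
  invisible(x)
}

evaluate_lhs <- function(ct, assignment) {
  sum(ct$coefs * assignment[names(ct$coefs)])
}

assignment_feasible <- function(model, assignment, tol = 1e-6) {
  all(vapply(model$constraints, function(ct) {
    lhs <- evaluate_lhs(ct, assignment)
    sl <- tol * max(1, abs(ct$rhs))
    switch(ct$dir,
           "<=" = lhs <= ct$rhs + sl,
           ">=" = lhs >= ct$rhs - sl,
           "==" = abs(lhs - ct$rhs) <= sl)
  }, logical(1)))
}

model_objective_value <- function(model, assignment) {
  sum(model$objective * assignment[names(model$objective)])
}

solver_python <- function() {
  py <- getOption("splitdiv.python", Sys.getenv("SPLITDIV_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  py
}

#' Solve a batch of 0/1 ILP models exactly
#'
#' Hands the models to the HiGHS branch-and-bound solver (through
#' `scipy.optimize.milp` in a Python subprocess) in one batched call, then
#' verifies every `optimal` assignment against the constraints in R. A
#' status of `"optimal"` is a proof of optimality from an exact solver;
#' infeasibility is reported as such, never as an empty optimum.
#'
#' @param models List of `ilp_model` objects.
#' @param time_limit Per-model wall-clock limit in seconds.
#' @param seed Integer recorded with the run (HiGHS itself is
#'   deterministic for these models).
#' @return List of `solve_result` objects with fields `status`
#'   (`"optimal"`, `"infeasible"` or `"limit-reached"`), `assignment`
#'   (named 0/1 vector) and `objective`.
#' @export
solve_ilp_batch <- function(models, time_limit = 60, seed = NULL) {
  stopifnot(length(models) >= 1L)
  lapply(models, function(m) stopifnot(inherits(m, "ilp_model")))
  py <- solver_python()
  script <- system.file("python", "milp_solve.py", package = "splitdiv")
  if (!nzchar(py) || !nzchar(script)) {
    stop("no exact MILP backend available: expected a `python` interpreter ",
         "providing scipy.optimize.milp (HiGHS) on the PATH", call. = FALSE)
  }
  payload <- list(
    time_limit = time_limit,
    models = lapply(models, function(m) {
      list(
        sense = m$sense,
        vars = as.list(m$vars),
        obj = as.list(m$objective),
        constraints = lapply(m$constraints, function(ct) {
          list(coefs = as.list(ct$coefs), dir = ct$dir, rhs = ct$rhs)
        })
      )
    })
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  code <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = "")
  if (code != 0L || !file.exists(fout)) {
    stop("MILP backend failed (exit ", code, "); expected scipy.optimize.milp ",
         "(HiGHS) to be importable by ", py, call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    r <- res[[i]]
    m <- models[[i]]
    status <- r$status
    assignment <- NULL
    objective <- NA_real_
    if (identical(status, "optimal")) {
      assignment <- stats::setNames(
        as.numeric(round(unlist(r$x))), m$vars)
      if (!assignment_feasible(m, assignment)) {
        stop("solver returned an assignment violating the constraints",
             call. = FALSE)
      }
      objective <- model_objective_value(m, assignment)
      if (abs(objective - as.numeric(r$objective)) >
          1e-6 * max(1, abs(objective))) {
        stop("solver objective disagrees with recomputed objective",
             call. = FALSE)
      }
    }
    out[[i]] <- structure(
      list(status = status, assignment = assignment, objective = objective,
           seed = seed),
      class = "solve_result"
    )
  }
  out
}

#' Solve a single 0/1 ILP model exactly
#'
#' @inheritParams solve_ilp_batch
#' @param model An `ilp_model`.
#' @return A `solve_result`; see [solve_ilp_batch()].
#' @export
solve_ilp <- function(model, time_limit = 60, seed = NULL) {
  solve_ilp_batch(list(model), time_limit = time_limit, seed = seed)[[1L]]
}

#' @export
print.solve_result <- function(x, ...) {
  cat("ILP solve:", x$status)
  if (identical(x$status, "optimal")) cat(", objective", format(x$objective))
  cat("\n")
  invisible(x)
}

#' Deterministic tie-break: lexicographically smallest optimal solution
#'
#' Among all optimal assignments, returns the one whose 0/1 vector (in
#' variable order restricted to `over`) is lexicographically smallest, by
#' iteratively re-solving with variables tentatively fixed to 0. Optimality
#' of the objective is preserved exactly (within `tol`).
#'
#' @param model An `ilp_model`.
#' @param over Variable names to normalize over (default: all).
#' @param tol Allowed objective slack when fixing variables.
#' @inheritParams solve_ilp_batch
#' @export
solve_ilp_lex <- function(model, over = model$vars, time_limit = 60,
                          seed = NULL, tol = 1e-9) {
  base <- solve_ilp(model, time_limit = time_limit, seed = seed)
  if (!identical(base$status, "optimal")) return(base)
  opt <- base$objective
  bound <- lin_constraint(
    model$objective,
    if (model$sense == "min") "<=" else ">=",
    opt + if (model$sense == "min") tol * max(1, abs(opt)) else
      -tol * max(1, abs(opt))
  )
  fixed <- list()
  cur <- base
  for (v in over) {
    if (cur$assignment[[v]] == 0) {
      fixed[[length(fixed) + 1L]] <- lin_constraint(
        stats::setNames(1, v), "==", 0)
      next
    }
    trial <- ilp_model(model$sense, model$objective,
                       c(model$constraints, list(bound), fixed,
                         list(lin_constraint(stats::setNames(1, v), "==", 0))),
                       vars = model$vars)
    r <- solve_ilp(trial, time_limit = time_limit, seed = seed)
    if (identical(r$status, "optimal")) {
      fixed[[length(fixed) + 1L]] <- lin_constraint(
        stats::setNames(1, v), "==", 0)
      cur <- r
    } else {
      fixed[[length(fixed) + 1L]] <- lin_constraint(
        stats::setNames(1, v), "==", 1)
    }
  }
  cur
}

#' Export a model in LP format
#'
#' Writes the standard LP file dialect (CPLEX-style) for debugging or for
#' feeding the model to an external solver.
#'
#' @param model An `ilp_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  term_str <- function(coefs) {
    if (length(coefs) == 0L) return("0")
    parts <- vapply(seq_along(coefs), function(i) {
      v <- coefs[i]
      sgn <- if (v >= 0) "+" else "-"
      paste(sgn, format(abs(v), scientific = FALSE), names(coefs)[i])
    }, character(1))
    sub("^\\+ ", "", paste(parts, collapse = " "))
  }
  lines <- c(
    if (model$sense == "min") "Minimize" else "Maximize",
    paste(" obj:", term_str(model$objective)),
    "Subject To"
  )
  for (i in seq_along(model$constraints)) {
    ct <- model$constraints[[i]]
    nm <- if (is.null(ct$name)) paste0("c", i) else ct$name
    dir <- c("<=" = "<=", ">=" = ">=", "==" = "=")[ct$dir]
    lines <- c(lines, paste0(" ", nm, ": ", term_str(ct$coefs), " ", dir,
                             " ", format(ct$rhs, scientific = FALSE)))
  }
  lines <- c(lines, "Binary", paste0(" ", model$vars), "End")
  writeLines(lines, path)
  invisible(path)
}
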