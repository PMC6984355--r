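#' Specify a recursive path model
#'
#' Builds a recursive (acyclic) linear path model over observed variables
#' from equation strings of the form `"M1 ~ b1*X + b7*C"`, one per
#' endogenous variable.  Variables that never appear on a left-hand side are
#' exogenous; their means and variances are free parameters.  An optional
#' constraint string such as `"b1*b2*b3 == 0"` declares the product of
#' coefficients whose null value is to be tested.
#'
#' The model is held internally in "all-y" form: a single coefficient matrix
#' over all observed variables plus a diagonal residual/exogenous covariance,
#' so that implied moments, likelihoods, and the semi-parametric null
#' transform all operate on the full variable set with one code path.
#'
#' @param equations character vector of equation strings, one per endogenous
#'   variable, e.g. `c("M1 ~ b1*X", "M2 ~ b2*M1 + b4*X")`.  Every predictor
#'   term must be written as `label*variable`; coefficient labels must be
#'   unique across the model.
#' @param constraint optional constraint string `"l1*l2*... == c"` naming
#'   coefficient labels whose product is constrained (default constant 0 when
#'   `== c` is omitted).
#' @return an object of class `"path_model"` with components
#'   `vars` (all variable names in topological order), `equations` (per
#'   endogenous variable, a named character vector mapping predictor variable
#'   to coefficient label), `exogenous`, `coef_table` (label, outcome,
#'   predictor), and `constraint` (list with `labels`, `constant`) or `NULL`.
#' @examples
#' m <- path_model(c("M1 ~ b1*X", "M2 ~ b2*M1 + b4*X",
#'                   "Y ~ b3*M2 + b5*M1 + b6*X"),
#'                 constraint = "b1*b2*b3 == 0")
#' m
#' @seealso [two_mediator_model()] for the sequential two-mediator chain,
#'   [implied_moments()], [fit_full()], [mbco_test()]
#' @export
path_model <- function(equations, constraint = NULL) {
  eqs <- lapply(equations, parse_equation)
  lhs <- vapply(eqs, `[[`, "", "response")
  if (anyDuplicated(lhs))
    stop("multiple equations for variable(s): ",
         paste(unique(lhs[duplicated(lhs)]), collapse = ", "))
  names(eqs) <- lhs
  all_vars <- unique(c(lhs, unlist(lapply(eqs, function(e) names(e$coef)))))
  exo <- setdiff(all_vars, lhs)

  labels <- unlist(lapply(eqs, `[[`, "coef"), use.names = FALSE)
  if (anyDuplicated(labels))
    stop("coefficient labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))

  edges <- lapply(eqs, function(e) names(e$coef))
  ord <- topological_sort(all_vars, edges)

  coef_table <- do.call(rbind, lapply(lhs, function(v) {
    data.frame(label = unname(eqs[[v]]$coef), outcome = v,
               predictor = names(eqs[[v]]$coef), stringsAsFactors = FALSE)
  }))

  cons <- if (!is.null(constraint)) parse_constraint(constraint, labels)

  structure(list(
    vars = ord,
    equations = lapply(eqs, `[[`, "coef")[intersect(ord, lhs)],
    exogenous = intersect(ord, exo),
    coef_table = coef_table,
    constraint = cons
  ), class = "path_model")
}

parse_equation <- function(txt) {
  parts <- strsplit(txt, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("equation must contain exactly one '~': ", txt)
  response <- trimws(parts[1])
  terms <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("equation has no predictors: ", txt)
  coef <- character(length(terms))
  pred <- character(length(terms))
  for (i in seq_along(terms)) {
    tp <- trimws(strsplit(terms[i], "*", fixed = TRUE)[[1]])
    if (length(tp) != 2L)
      stop("each term must be written label*variable: '", terms[i], "'")
    coef[i] <- tp[1]; pred[i] <- tp[2]
  }
  if (anyDuplicated(pred))
    stop("duplicated predictor in equation: ", txt)
  names(coef) <- pred
  list(response = response, coef = coef)
}

parse_constraint <- function(txt, labels) {
  parts <- strsplit(txt, "==", fixed = TRUE)[[1]]
  constant <- if (length(parts) == 2L) {
    v <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(v)) stop("constraint constant is not numeric: ", txt)
    v
  } else if (length(parts) == 1L) 0 else
    stop("constraint must contain at most one '==': ", txt)
  lab <- trimws(strsplit(parts[1], "*", fixed = TRUE)[[1]])
  lab <- lab[nzchar(lab)]
  if (length(lab) < 1L) stop("empty constraint: ", txt)
  missing <- setdiff(lab, labels)
  if (length(missing))
    stop("constraint names unknown coefficient(s): ",
         paste(missing, collapse = ", "))
  list(labels = lab, constant = constant)
}

# Kahn's algorithm; edges[[v]] = predecessors of v (may be NULL for exogenous)
topological_sort <- function(vars, edges) {
  indeg <- vapply(vars, function(v) length(edges[[v]]), 0L)
  names(indeg) <- vars
  out <- character(0)
  ready <- vars[indeg == 0L]
  remaining <- vars
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    for (w in remaining) {
      if (v %in% edges[[w]]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) ready <- c(ready, w)
      }
    }
  }
  if (length(remaining))
    stop("model is not recursive; cycle among: ",
         paste(remaining, collapse = ", "))
  out
}

#' Topological order of a path model's variables
#'
#' Every variable follows all of its predictors; exogenous variables come
#' first.  The order is computed at construction time (a cyclic system is
#' rejected by [path_model()]), so this is an accessor.
#'
#' @param model a `path_model`
#' @return character vector of variable names
#' @export
topological_order <- function(model) {
  stopifnot(inherits(model, "path_model"))
  model$vars
}

#' Read a path model from a YAML file
#'
#' The file must have an `equations` sequence of equation strings and may
#' have a scalar `constraint` string, mirroring [path_model()]'s arguments.
#'
#' @param path file path
#' @return a `path_model`
#' @export
read_path_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$equations)) stop("YAML model needs an 'equations' field")
  path_model(unlist(cfg$equations), constraint = cfg$constraint)
}

#' The sequential two-mediator mediation model
#'
#' Convenience constructor for the chain X -> M1 -> M2 -> Y with all direct
#' paths included (M2 ~ X, Y ~ M1, Y ~ X) and, optionally, a covariate C
#' entering every equation.  The indirect effect of X on Y transmitted
#' through both mediators is the product b1*b2*b3, declared as the model's
#' test constraint (`b1*b2*b3 == 0`).
#'
#' @param covariate include covariate C in all three equations?
#' @return a `path_model`
#' @export
two_mediator_model <- function(covariate = FALSE) {
  eqs <- if (covariate) c(
    "M1 ~ b1*X + b7*C",
    "M2 ~ b2*M1 + b4*X + b8*C",
    "Y ~ b3*M2 + b5*M1 + b6*X + b9*C"
  ) else c(
    "M1 ~ b1*X",
    "M2 ~ b2*M1 + b4*X",
    "Y ~ b3*M2 + b5*M1 + b6*X"
  )
  path_model(eqs, constraint = "b1*b2*b3 == 0")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Recursive path model (", length(x$vars), " variables)\n", sep = "")
  cat("  order:", paste(x$vars, collapse = " -> "), "\n")
  for (v in names(x$equations)) {
    rhs <- paste(paste0(x$equations[[v]], "*", names(x$equations[[v]])),
                 collapse = " + ")
    cat("  ", v, " ~ ", rhs, "\n", sep = "")
  }
  if (length(x$exogenous))
    cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  if (!is.null(x$constraint))
    cat("  test: ", paste(x$constraint$labels, collapse = "*"), " == ",
        x$constraint$constant, "\n", sep = "")
  invisible(x)
}
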