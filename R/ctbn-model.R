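#' Construct a continuous-time Bayesian network model
#'
#' A CTBN factors a joint continuous-time Markov process over a set of
#' discrete variables: each variable evolves with transition intensities that
#' depend only on the current states of its parent variables. For every
#' variable and every joint configuration of its parents there is one
#' conditional intensity matrix (CIM): a square matrix with non-negative
#' off-diagonal rates (per hour) and rows summing to zero.
#'
#' @param variables Character vector of variable (gene) names.
#' @param n_states Integer: number of states per variable. Either a single
#'   value recycled to all variables or a named vector over `variables`.
#' @param parents Named list mapping each variable to a character vector of
#'   parent variable names. Variables absent from the list get no parents.
#' @param cims Named list: `cims[[v]]` is a list of CIMs for variable `v`,
#'   one per parent configuration, indexed by [parent_config_index()]. If
#'   `NULL`, an intensity-free shell is built (useful for structures only).
#' @param init Named integer vector of initial states (0-based), or `NULL`
#'   for the middle state `floor((k - 1) / 2)` of each variable.
#'
#' @return An object of class `ctbn_model`.
#' @seealso [generate_model()], [sample_trajectory()], [tidy.ctbn_model()]
#' @export
ctbn_model <- function(variables, n_states, parents = list(), cims = NULL,
                       init = NULL) {
  stopifnot(is.character(variables), length(variables) >= 1,
            !anyDuplicated(variables))
  if (length(n_states) == 1) {
    n_states <- stats::setNames(rep(as.integer(n_states), length(variables)),
                                variables)
  }
  n_states <- n_states[variables]
  if (anyNA(n_states) || any(n_states < 2)) {
    rlang::abort("every variable needs n_states >= 2")
  }
  full_parents <- stats::setNames(vector("list", length(variables)), variables)
  for (v in variables) full_parents[[v]] <- as.character(parents[[v]] %||% character())
  for (v in variables) {
    ps <- full_parents[[v]]
    if (!all(ps %in% variables)) {
      rlang::abort(paste0("unknown parent(s) of ", v, ": ",
                          paste(setdiff(ps, variables), collapse = ", ")))
    }
    if (v %in% ps) rlang::abort(paste0("variable ", v, " cannot be its own parent"))
  }
  if (is.null(init)) {
    init <- stats::setNames(as.integer((n_states - 1L) %/% 2L), variables)
  }
  model <- structure(
    list(variables = variables, n_states = n_states,
         parents = full_parents, cims = cims, init = init[variables]),
    class = "ctbn_model")
  if (!is.null(cims)) validate_cims(model)
  model
}

validate_cims <- function(model) {
  for (v in model$variables) {
    k <- model$n_states[[v]]
    n_conf <- prod(model$n_states[model$parents[[v]]])
    cl <- model$cims[[v]]
    if (length(cl) != n_conf) {
      rlang::abort(paste0(v, ": expected ", n_conf, " CIMs, got ", length(cl)))
    }
    for (cim in cl) {
      if (!is.matrix(cim) || any(dim(cim) != k)) {
        rlang::abort(paste0(v, ": CIM must be ", k, "x", k))
      }
      off <- cim; diag(off) <- 0
      if (any(off < 0)) rlang::abort(paste0(v, ": negative off-diagonal intensity"))
      if (any(abs(rowSums(cim)) > 1e-8)) {
        rlang::abort(paste0(v, ": CIM rows must sum to 0"))
      }
    }
  }
  invisible(model)
}

#' Index of a parent-state configuration
#'
#' Maps joint parent states (0-based) to a 1-based configuration index with
#' the first parent varying fastest: `1 + s1 + k1*s2 + k1*k2*s3 + ...`.
#' This is the indexing convention for CIM lists and sufficient statistics.
#'
#' @param states Integer vector (one configuration) or matrix with one column
#'   per parent (many configurations), 0-based states.
#' @param cards Integer vector of parent cardinalities, same order.
#' @return Integer configuration index (vector if `states` is a matrix).
#' @export
parent_config_index <- function(states, cards) {
  if (length(cards) == 0) {
    n <- if (is.matrix(states)) nrow(states) else 1L
    return(rep(1L, n))
  }
  mult <- cumprod(c(1L, cards[-length(cards)]))
  if (is.matrix(states)) {
    as.integer(1L + states %*% mult)
  } else {
    as.integer(1L + sum(states * mult))
  }
}

#' Enumerate all parent configurations
#'
#' @param cards Integer vector of parent cardinalities.
#' @return Integer matrix, one row per configuration in index order.
#' @keywords internal
enumerate_configs <- function(cards) {
  if (length(cards) == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  as.matrix(rev(expand.grid(rev(lapply(cards, function(k) 0:(k - 1L))))))
}

#' @export
print.ctbn_model <- function(x, ...) {
  n_arcs <- sum(lengths(x$parents))
  cat("<ctbn_model> ", length(x$variables), " variables, ", n_arcs,
      " arcs, states: ", paste(unique(x$n_states), collapse = "/"),
      if (is.null(x$cims)) " (structure only)" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a CTBN model into its arc list
#'
#' @param x A `ctbn_model`.
#' @param ... Unused.
#' @return A tibble with columns `from` and `to`, one row per regulatory arc
#'   (parent -> child).
#' @method tidy ctbn_model
#' @export
tidy.ctbn_model <- function(x, ...) {
  arcs <- purrr::imap(x$parents, function(ps, child) {
    tibble::tibble(from = as.character(ps), to = rep(child, length(ps)))
  })
  dplyr::arrange(dplyr::bind_rows(arcs), .data$from, .data$to)
}

#' @rdname tidy.ctbn_model
#' @return For `glance()`: a one-row tibble with variable, arc and state counts.
#' @method glance ctbn_model
#' @export
glance.ctbn_model <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variables),
    n_arcs = sum(lengths(x$parents)),
    max_in_degree = if (length(x$parents)) max(lengths(x$parents)) else 0L,
    n_states_min = min(x$n_states),
    n_states_max = max(x$n_states))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
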