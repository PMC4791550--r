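#' Learning settings for CTBN structure search
#'
#' The marginal-likelihood family score integrates the intensity and
#' transition-probability parameters out under conjugate priors: each
#' leave-state intensity q gets a Gamma(alpha + 1, tau) prior (pseudo-count
#' `alpha`, pseudo-dwell `tau` hours) and each row of the jump distribution a
#' symmetric Dirichlet(alpha) prior over the k - 1 target states.
#'
#' @param alpha Prior pseudo-count (> 0). Default 0.01.
#' @param tau Prior pseudo-dwell time in hours (> 0). Default 5.
#' @param max_parents Maximum parent-set size per variable. Default 5.
#' @param search `"greedy"` (hill-climbing) or `"exhaustive"` (exact, small
#'   problems only).
#' @param exhaustive_cap Refuse exhaustive search when the number of
#'   candidate families exceeds this.
#' @return A `learn_config` list.
#' @export
learn_config <- function(alpha = 0.01, tau = 5, max_parents = 5L,
                         search = c("greedy", "exhaustive"),
                         exhaustive_cap = 20000L) {
  search <- match.arg(search)
  if (alpha <= 0) rlang::abort("alpha must be > 0")
  if (tau <= 0) rlang::abort("tau must be > 0")
  if (max_parents < 0) rlang::abort("max_parents must be >= 0")
  structure(list(alpha = alpha, tau = tau, max_parents = as.integer(max_parents),
                 search = search, exhaustive_cap = as.integer(exhaustive_cap)),
            class = "learn_config")
}

#' Build a trajectory from point observations
#'
#' Converts states observed at grid times into a piecewise-constant path:
#' the state observed at `t_i` holds on `[t_i, t_{i+1})`; when consecutive
#' observations differ, the transition is recorded at `t_{i+1}`; the final
#' observation contributes a zero-dwell segment at the last time.
#'
#' @param obs A tibble with column `time_h` and one 0-based integer state
#'   column per variable (one observation series).
#' @param trajectory_id Id assigned to the resulting trajectory.
#' @return A `ctbn_trajectory` tibble.
#' @export
trajectory_from_observations <- function(obs, trajectory_id = 1L) {
  stopifnot("time_h" %in% names(obs), nrow(obs) >= 2)
  if (is.unsorted(obs$time_h, strictly = TRUE)) {
    rlang::abort("observation times must be strictly increasing")
  }
  vars <- setdiff(names(obs), "time_h")
  tt <- obs$time_h
  n <- length(tt)
  out <- tibble::tibble(trajectory_id = as.integer(trajectory_id),
                        t_start = tt, t_end = c(tt[-1], tt[n]))
  out <- dplyr::bind_cols(out, tibble::as_tibble(obs[vars]))
  new_trajectory(out, vars)
}

#' Trajectories from a discretized state table
#'
#' Each replicate's state series becomes one independent trajectory; their
#' sufficient statistics are pooled during learning.
#'
#' @param states A `ctbn_states` tibble (`gene`, `time_h`, `replicate`,
#'   `state`), e.g. from [discretize_fc()].
#' @return A `ctbn_trajectory` tibble with one id per replicate.
#' @export
trajectories_from_states <- function(states) {
  stopifnot(all(c("gene", "time_h", "replicate", "state") %in% names(states)))
  reps <- sort(unique(states$replicate))
  trajs <- purrr::imap(reps, function(r, i) {
    wide <- states |>
      dplyr::filter(.data$replicate == r) |>
      dplyr::select("gene", "time_h", "state") |>
      tidyr::pivot_wider(names_from = "gene", values_from = "state") |>
      dplyr::arrange(.data$time_h)
    if (anyNA(wide)) rlang::abort("missing (gene, time) state in replicate series")
    trajectory_from_observations(wide, trajectory_id = i)
  })
  vars <- sort(unique(states$gene))
  new_trajectory(dplyr::bind_rows(trajs), vars)
}

# Compiled evidence: segment state matrix, durations, per-variable transitions.
compile_evidence <- function(traj, n_states = NULL) {
  vars <- trajectory_variables(traj)
  df <- as.data.frame(traj)
  S <- as.matrix(df[, vars, drop = FALSE])
  storage.mode(S) <- "integer"
  dur <- df$t_end - df$t_start
  if (any(dur < -1e-9)) rlang::abort("negative segment duration")
  id <- df$trajectory_id
  if (is.null(n_states)) {
    cards <- apply(S, 2, max) + 1L
    cards <- pmax(cards, 2L)
  } else if (length(n_states) == 1) {
    cards <- stats::setNames(rep(as.integer(n_states), length(vars)), vars)
  } else {
    cards <- as.integer(n_states[vars])
  }
  cards <- stats::setNames(as.integer(cards), vars)
  if (any(S >= rep(cards, each = nrow(S)))) {
    rlang::abort("observed state exceeds declared n_states")
  }
  n <- nrow(S)
  same <- if (n > 1) id[-1] == id[-n] else logical(0)
  trans <- lapply(seq_along(vars), function(j) {
    chg <- which(same & S[-1, j] != S[-n, j])
    list(seg = chg, from = S[chg, j], to = S[chg + 1L, j])
  })
  names(trans) <- vars
  list(vars = vars, cards = cards, S = S, dur = dur, id = id, trans = trans,
       total_dur = sum(dur))
}

# Dwell/transition tallies for one family, from compiled evidence.
family_tallies <- function(ev, x, pidx) {
  k <- ev$cards[[x]]
  pcards <- ev$cards[pidx]
  C <- prod(pcards)
  u <- parent_config_index(ev$S[, pidx, drop = FALSE], pcards)
  cell <- ev$S[, x] + 1L + k * (u - 1L)
  Tm <- numeric(k * C)
  agg <- rowsum(ev$dur, cell)
  Tm[as.integer(rownames(agg))] <- agg
  Tm <- matrix(Tm, nrow = k)
  tr <- ev$trans[[x]]
  M <- array(0L, c(k, k, C))
  if (length(tr$seg)) {
    useg <- u[tr$seg]
    lin <- (tr$from + 1L) + k * tr$to + k * k * (useg - 1L)
    M <- array(tabulate(lin, k * k * C), c(k, k, C))
  }
  list(T = Tm, M = M, k = k, C = C)
}

#' Sufficient statistics of one CTBN family
#'
#' Accumulates, over all trajectories, the dwell time `T[x; u]` spent by
#' `variable` in each of its states under each parent configuration `u`, and
#' the transition counts `M[x, x'; u]`. A transition is attributed to the
#' parent configuration in force immediately before it. Replicate
#' trajectories pool additively.
#'
#' @param traj A `ctbn_trajectory` tibble (any number of trajectory ids).
#' @param variable Variable name.
#' @param parents Character vector of parent names (possibly empty).
#' @param n_states Scalar or named vector of state counts; inferred from the
#'   data when `NULL`.
#' @return A `ctbn_suffstats`: list with `T` (k x n_config matrix), `M`
#'   (k x k x n_config array), `variable`, `parents`, `cards`.
#' @export
sufficient_statistics <- function(traj, variable, parents = character(),
                                  n_states = NULL) {
  ev <- compile_evidence(traj, n_states)
  if (!variable %in% ev$vars) {
    rlang::abort(paste0("variable ", variable, " absent from trajectories"))
  }
  if (!all(parents %in% ev$vars)) {
    rlang::abort(paste0("parent(s) absent from trajectories: ",
                        paste(setdiff(parents, ev$vars), collapse = ", ")))
  }
  ft <- family_tallies(ev, variable, match(parents, ev$vars))
  structure(list(T = ft$T, M = ft$M, variable = variable,
                 parents = as.character(parents),
                 cards = ev$cards[c(variable, parents)]),
            class = "ctbn_suffstats")
}

#' @export
print.ctbn_suffstats <- function(x, ...) {
  cat("<ctbn_suffstats> ", x$variable,
      if (length(x$parents)) paste0(" | ", paste(x$parents, collapse = ", ")) else "",
      ": total dwell ", signif(sum(x$T), 4), " h, ",
      sum(x$M), " transitions\n", sep = "")
  invisible(x)
}

# Core closed-form marginal likelihood; Tm is k x C, M is k x k x C.
score_from_tallies <- function(Tm, M, alpha, tau) {
  k <- nrow(Tm)
  if (k < 2) return(0)
  Mx <- apply(M, c(1, 3), sum)
  ln_q <- sum(lgamma(alpha + Mx + 1) - lgamma(alpha + 1) +
                (alpha + 1) * log(tau) - (alpha + Mx + 1) * log(tau + Tm))
  a_row <- alpha * (k - 1)
  # diagonal of M is structurally zero, so its lgamma terms cancel
  ln_theta <- sum(lgamma(a_row) - lgamma(a_row + Mx)) +
    sum(lgamma(alpha + M) - lgamma(alpha))
  ln_q + ln_theta
}

#' Log marginal likelihood of one family
#'
#' Closed-form evidence of a family's dwell and transition data with the
#' CIM parameters integrated out: each leave intensity under a
#' Gamma(alpha + 1, tau) prior, each jump-distribution row under a symmetric
#' Dirichlet(alpha). With no data the score is exactly 0 (marginal
#' likelihood 1). Holding counts fixed, the score strictly decreases in any
#' dwell time.
#'
#' @param stats A `ctbn_suffstats` from [sufficient_statistics()].
#' @param config A [learn_config()] providing `alpha` and `tau`.
#' @return The log marginal likelihood (finite for valid statistics).
#' @export
family_log_score <- function(stats, config = learn_config()) {
  stopifnot(inherits(stats, "ctbn_suffstats"))
  if (config$alpha <= 0 || config$tau <= 0) {
    rlang::abort("alpha and tau must be > 0")
  }
  score_from_tallies(stats$T, stats$M, config$alpha, config$tau)
}

#' Total network score (sum of family scores)
#'
#' CTBN structure scores decompose over families, so the network score of a
#' candidate structure is the sum of [family_log_score()] over variables.
#'
#' @param traj A `ctbn_trajectory` tibble.
#' @param parent_sets Named list mapping each variable to its parents.
#' @param config A [learn_config()].
#' @param n_states Scalar or named vector of state counts.
#' @return The total log score.
#' @export
network_log_score <- function(traj, parent_sets, config = learn_config(),
                              n_states = NULL) {
  ev <- compile_evidence(traj, n_states)
  tot <- 0
  for (v in ev$vars) {
    ps <- as.character(parent_sets[[v]] %||% character())
    if (length(ps) > config$max_parents) {
      rlang::abort(paste0(v, ": parent set exceeds max_parents"))
    }
    ft <- family_tallies(ev, v, match(ps, ev$vars))
    tot <- tot + score_from_tallies(ft$T, ft$M, config$alpha, config$tau)
  }
  tot
}

# Memoized family score over a compiled-evidence environment.
make_scorer <- function(ev, config) {
  cache <- new.env(parent = emptyenv())
  function(x, pidx) {
    key <- paste0(x, "|", paste(sort(pidx), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    ft <- family_tallies(ev, ev$vars[x], pidx)
    s <- score_from_tallies(ft$T, ft$M, config$alpha, config$tau)
    cache[[key]] <- s
    s
  }
}

#' Greedy hill-climbing structure search
#'
#' Optimizes each variable's parent set independently (CTBN structures may
#' contain cycles, so there is no acyclicity constraint). Starting from the
#' empty set, the single add-or-remove-parent move with the largest strictly
#' positive score gain is applied until a local optimum is reached or
#' additions would exceed `max_parents`. Ties are broken deterministically:
#' additions before removals, lower variable index first.
#'
#' @param traj A `ctbn_trajectory` tibble.
#' @param config A [learn_config()].
#' @param n_states Scalar or named vector of state counts (inferred when
#'   `NULL`; pass explicitly when some states are unobserved).
#' @return A `ctbn_fit`: list with `parents`, `family_scores`, `log_score`,
#'   `variables`, `n_states`, `config`, `search`.
#' @export
greedy_structure_search <- function(traj, config = learn_config(),
                                    n_states = NULL) {
  ev <- compile_evidence(traj, n_states)
  sc <- make_scorer(ev, config)
  nv <- length(ev$vars)
  parents <- stats::setNames(vector("list", nv), ev$vars)
  fam_scores <- stats::setNames(numeric(nv), ev$vars)
  for (x in seq_len(nv)) {
    cur <- integer(0)
    cur_s <- sc(x, cur)
    repeat {
      best_gain <- 0
      best_set <- NULL
      cands <- list()
      if (length(cur) < config$max_parents) {
        for (p in setdiff(seq_len(nv)[-x], cur)) {
          cands[[length(cands) + 1L]] <- sort(c(cur, p))
        }
      }
      for (p in cur) cands[[length(cands) + 1L]] <- setdiff(cur, p)
      for (cand in cands) {
        s <- sc(x, cand)
        if (s - cur_s > best_gain) {
          best_gain <- s - cur_s
          best_set <- cand
        }
      }
      if (is.null(best_set)) break
      cur <- best_set
      cur_s <- cur_s + best_gain
    }
    parents[[x]] <- ev$vars[cur]
    fam_scores[[x]] <- cur_s
  }
  new_ctbn_fit(parents, fam_scores, ev, config, "greedy")
}

#' Exhaustive (exact) structure search
#'
#' Enumerates every candidate parent set of size at most `max_parents` for
#' every variable and returns the score-optimal structure. Intended as an
#' exact oracle on small problems; refuses to run when the number of
#' candidate families exceeds `config$exhaustive_cap`.
#'
#' @inheritParams greedy_structure_search
#' @return A `ctbn_fit` (see [greedy_structure_search()]).
#' @export
exhaustive_structure_search <- function(traj, config = learn_config(),
                                        n_states = NULL) {
  ev <- compile_evidence(traj, n_states)
  nv <- length(ev$vars)
  mp <- min(config$max_parents, nv - 1L)
  n_fam <- nv * sum(choose(nv - 1, 0:mp))
  if (n_fam > config$exhaustive_cap) {
    rlang::abort(sprintf(
      "exhaustive search refused: %d candidate families exceed the cap of %d",
      n_fam, config$exhaustive_cap))
  }
  sc <- make_scorer(ev, config)
  parents <- stats::setNames(vector("list", nv), ev$vars)
  fam_scores <- stats::setNames(numeric(nv), ev$vars)
  for (x in seq_len(nv)) {
    others <- seq_len(nv)[-x]
    best_s <- -Inf
    best_set <- integer(0)
    for (sz in 0:mp) {
      sets <- if (sz == 0) list(integer(0)) else {
        cmb <- utils::combn(others, sz)
        lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
      }
      for (cand in sets) {
        s <- sc(x, cand)
        if (s > best_s) {
          best_s <- s
          best_set <- cand
        }
      }
    }
    parents[[x]] <- ev$vars[best_set]
    fam_scores[[x]] <- best_s
  }
  new_ctbn_fit(parents, fam_scores, ev, config, "exhaustive")
}

new_ctbn_fit <- function(parents, fam_scores, ev, config, search) {
  structure(list(parents = parents, family_scores = fam_scores,
                 log_score = sum(fam_scores), variables = ev$vars,
                 n_states = ev$cards, config = config, search = search,
                 n_trajectories = length(unique(ev$id)),
                 total_duration = ev$total_dur,
                 n_transitions = sum(lengths(lapply(ev$trans, `[[`, "seg")))),
            class = "ctbn_fit")
}

#' Learn a CTBN structure from discretized states or trajectories
#'
#' Front door to the learner: accepts either a `ctbn_states` table (each
#' replicate becomes an independent trajectory) or a `ctbn_trajectory`
#' tibble, and dispatches to greedy or exhaustive search per
#' `config$search`.
#'
#' @param x A `ctbn_states` or `ctbn_trajectory` object.
#' @param config A [learn_config()].
#' @param n_states State counts (default 3 for discretized fold changes).
#' @return A `ctbn_fit`.
#' @export
learn_ctbn <- function(x, config = learn_config(), n_states = NULL) {
  if (inherits(x, "ctbn_states")) {
    traj <- trajectories_from_states(x)
    if (is.null(n_states)) n_states <- 3L
  } else if (inherits(x, "ctbn_trajectory")) {
    traj <- x
  } else {
    rlang::abort("x must be a ctbn_states or ctbn_trajectory object")
  }
  if (config$search == "greedy") {
    greedy_structure_search(traj, config, n_states)
  } else {
    exhaustive_structure_search(traj, config, n_states)
  }
}

#' @export
print.ctbn_fit <- function(x, ...) {
  cat("<ctbn_fit> ", x$search, " search: ", length(x$variables), " variables, ",
      sum(lengths(x$parents)), " arcs, log score ", signif(x$log_score, 8), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a learned structure into its arc list
#'
#' @param x A `ctbn_fit`.
#' @param ... Unused.
#' @return A tibble `from`, `to`, `family_score` (the child family's score).
#' @method tidy ctbn_fit
#' @export
tidy.ctbn_fit <- function(x, ...) {
  arcs <- purrr::imap(x$parents, function(ps, child) {
    tibble::tibble(from = as.character(ps), to = rep(child, length(ps)),
                   family_score = rep(unname(x$family_scores[child]), length(ps)))
  })
  dplyr::arrange(dplyr::bind_rows(arcs), .data$from, .data$to)
}

#' @rdname tidy.ctbn_fit
#' @return For `glance()`: one-row tibble with score, arc count and data size.
#' @method glance ctbn_fit
#' @export
glance.ctbn_fit <- function(x, ...) {
  tibble::tibble(
    log_score = x$log_score, n_variables = length(x$variables),
    n_arcs = sum(lengths(x$parents)),
    max_in_degree = if (length(x$parents)) max(lengths(x$parents)) else 0L,
    n_trajectories = x$n_trajectories, total_duration_h = x$total_duration,
    n_transitions = x$n_transitions,
    alpha = x$config$alpha, tau = x$config$tau, search = x$search)
}

#' Posterior-mean conditional intensity matrices
#'
#' Bayesian parameter estimates for one family under the learning priors:
#' leave intensities `q(x|u) = (alpha + M[x;u] + 1) / (tau + T[x;u])` and
#' jump probabilities `theta(x -> x'|u) = (alpha + M[x,x';u]) /
#' (alpha (k-1) + M[x;u])`. Cells without data fall back to the prior mean,
#' e.g. `(alpha + 1) / tau`.
#'
#' @param stats A `ctbn_suffstats`.
#' @param config A [learn_config()].
#' @return A `ctbn_cim_posterior`: list with `q_hat` (k x n_config), `theta_hat`
#'   (k x k x n_config, zero diagonal, rows summing to 1) and `cims` (list of
#'   posterior-mean CIMs, rows summing to 0).
#' @export
estimate_parameters <- function(stats, config = learn_config()) {
  stopifnot(inherits(stats, "ctbn_suffstats"))
  alpha <- config$alpha; tau <- config$tau
  k <- nrow(stats$T); C <- ncol(stats$T)
  Mx <- apply(stats$M, c(1, 3), sum)
  q_hat <- (alpha + Mx + 1) / (tau + stats$T)
  theta_hat <- array(0, c(k, k, C))
  for (u in seq_len(C)) {
    for (x in seq_len(k)) {
      num <- alpha + stats$M[x, , u]
      num[x] <- 0
      theta_hat[x, , u] <- num / (alpha * (k - 1) + Mx[x, u])
    }
  }
  cims <- lapply(seq_len(C), function(u) {
    cim <- q_hat[, u] * theta_hat[, , u]
    diag(cim) <- -q_hat[, u]
    cim
  })
  structure(list(q_hat = q_hat, theta_hat = theta_hat, cims = cims,
                 variable = stats$variable, parents = stats$parents),
            class = "ctbn_cim_posterior")
}
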