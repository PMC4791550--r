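#' Configuration for the synthetic expression-bundle generator
#'
#' The generator emulates the study design the pipeline targets: a 10-point,
#' unevenly spaced time course over 72 hours, three biological replicates,
#' and a stimulated (case) versus unstimulated (control) condition. Signal
#' genes are driven by a known ground-truth CTBN; null genes carry no
#' condition effect; undetected probes fail the detection-p-value criterion.
#'
#' @param n_genes Number of signal genes driven by the ground-truth CTBN.
#' @param n_states States per gene (default 3: down / unchanged / up, the
#'   three fold-change bins used downstream).
#' @param max_true_parents Maximum parents per gene in the ground truth.
#' @param rate_scale Baseline leave-state intensity in 1/h. The default
#'   0.25/h gives a mean sojourn of 4 h, a scale on which a 72 h course with
#'   ten observations sees several regime changes per gene.
#' @param parent_effect Multiplicative rate modulation per parent: a parent
#'   in its highest state multiplies the child's leave rates by
#'   `parent_effect`, in its lowest state by `1/parent_effect`.
#' @param horizon Duration of the course in hours.
#' @param grid Observation times in hours; strictly increasing, starting at 0
#'   and ending at `horizon`. Default: 10 unevenly spaced points over 72 h.
#' @param n_replicates Biological replicates per condition.
#' @param level_map Numeric vector mapping state (0-based position) to the
#'   log2 fold-change center of expression. Defaults `c(-2, 0, 2)` put the
#'   centers two bin-widths apart so zero-noise discretization at bins
#'   (-1, 1) is unambiguous.
#' @param noise_sd Gaussian measurement noise SD on the log2 scale.
#' @param n_null_genes Genes with no condition effect in either arm.
#' @param n_undetected_probes Probes whose detection p-values fail the
#'   detection criterion in every sample.
#' @param seed Integer seed; every generator operation is reproducible.
#'
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genes,
                             n_states = 3L,
                             max_true_parents = 2L,
                             rate_scale = 0.25,
                             parent_effect = 3,
                             horizon = 72,
                             grid = c(0, 0.5, 1, 2, 4, 6, 12, 24, 48, 72),
                             n_replicates = 3L,
                             level_map = c(-2, 0, 2),
                             noise_sd = 0.2,
                             n_null_genes = 0L,
                             n_undetected_probes = 0L,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_states = as.integer(n_states),
              max_true_parents = as.integer(max_true_parents),
              rate_scale = rate_scale, parent_effect = parent_effect,
              horizon = horizon, grid = grid,
              n_replicates = as.integer(n_replicates), level_map = level_map,
              noise_sd = noise_sd, n_null_genes = as.integer(n_null_genes),
              n_undetected_probes = as.integer(n_undetected_probes),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  err <- character()
  if (cfg$n_genes < 1) err <- c(err, "n_genes must be >= 1")
  if (cfg$rate_scale <= 0) err <- c(err, "rate_scale must be > 0")
  if (cfg$parent_effect <= 0) err <- c(err, "parent_effect must be > 0")
  if (cfg$max_true_parents < 0 || cfg$max_true_parents >= cfg$n_genes) {
    err <- c(err, "max_true_parents must be in [0, n_genes - 1]")
  }
  g <- cfg$grid
  if (length(g) < 2 || is.unsorted(g, strictly = TRUE)) {
    err <- c(err, "grid must be strictly increasing with >= 2 points")
  } else {
    if (g[1] != 0) err <- c(err, "grid must start at 0")
    if (abs(g[length(g)] - cfg$horizon) > 1e-9) {
      err <- c(err, "grid must end at horizon")
    }
  }
  if (length(cfg$level_map) != cfg$n_states) {
    err <- c(err, "level_map must have one center per state")
  } else if (is.unsorted(cfg$level_map, strictly = TRUE)) {
    err <- c(err, "level_map centers must be strictly increasing")
  }
  if (cfg$noise_sd < 0) err <- c(err, "noise_sd must be >= 0")
  if (cfg$n_replicates < 1) err <- c(err, "n_replicates must be >= 1")
  if (length(err)) rlang::abort(c("invalid generator_config", err))
  cfg
}

#' Generate a ground-truth CTBN model
#'
#' Draws a random regulatory structure (each gene gets 0 to
#' `max_true_parents` parents) and builds its conditional intensity matrices.
#' Leave-state rates are `rate_scale` (with a per-gene, per-state jitter in
#' \[0.7, 1.3\]) multiplied by `parent_effect` raised to the sum of centered
#' parent states, so every ground-truth arc modulates the child's dwell-time
#' distribution and is identifiable from trajectory statistics. The jump
#' distribution out of a state is uniform over the other states.
#'
#' @param config A [generator_config()].
#' @return A `ctbn_model` with CIMs attached.
#' @export
generate_model <- function(config) {
  cfg <- validate_generator_config(config)
  withr::local_seed(cfg$seed)
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  k <- cfg$n_states
  parents <- stats::setNames(vector("list", cfg$n_genes), genes)
  for (i in seq_along(genes)) {
    np <- sample(0:cfg$max_true_parents, 1)
    parents[[i]] <- if (np > 0) sort(sample(genes[-i], np)) else character()
  }
  mid <- (k - 1) / 2
  cims <- stats::setNames(vector("list", cfg$n_genes), genes)
  for (g in genes) {
    base <- cfg$rate_scale * stats::runif(k, 0.7, 1.3)
    cards <- rep(k, length(parents[[g]]))
    confs <- enumerate_configs(cards)
    cims[[g]] <- lapply(seq_len(nrow(confs)), function(ci) {
      mult <- cfg$parent_effect ^ sum(confs[ci, ] - mid)
      cim <- matrix(0, k, k)
      for (x in seq_len(k)) {
        q <- base[x] * mult
        cim[x, -x] <- q / (k - 1)
        cim[x, x] <- -q
      }
      cim
    })
  }
  ctbn_model(genes, k, parents, cims)
}

#' Simulate a CTBN trajectory (Gillespie algorithm)
#'
#' Samples one piecewise-constant joint state path on `[0, horizon]`. Waiting
#' times come from the exponential race over the current leave-state
#' intensities of all variables; at each jump exactly one variable changes
#' state, chosen proportionally to its intensity, and its new state follows
#' the jump distribution of its CIM row.
#'
#' @param model A `ctbn_model` with CIMs.
#' @param horizon Duration in hours (> 0).
#' @param seed Integer seed.
#' @return A `ctbn_trajectory` tibble with columns `trajectory_id`,
#'   `t_start`, `t_end` and one 0-based integer state column per variable;
#'   segments are contiguous and consecutive segments differ in exactly one
#'   variable.
#' @export
sample_trajectory <- function(model, horizon = 72, seed = 1L) {
  stopifnot(inherits(model, "ctbn_model"), !is.null(model$cims), horizon > 0)
  withr::local_seed(as.integer(seed))
  vars <- model$variables
  nv <- length(vars)
  cards <- unname(model$n_states)
  pidx <- lapply(model$parents, function(ps) match(ps, vars))
  cims <- model$cims
  if (!is.null(names(cims))) cims <- cims[vars]
  state <- unname(model$init)

  leave_rate <- function(state) {
    vapply(seq_len(nv), function(i) {
      u <- parent_config_index(state[pidx[[i]]], cards[pidx[[i]]])
      -cims[[i]][[u]][state[i] + 1L, state[i] + 1L]
    }, numeric(1))
  }

  t_now <- 0
  seg_start <- numeric(0); seg_end <- numeric(0)
  seg_state <- matrix(integer(), ncol = nv)
  repeat {
    rates <- leave_rate(state)
    total <- sum(rates)
    t_next <- if (total <= 0) Inf else t_now + stats::rexp(1, total)
    t_stop <- min(t_next, horizon)
    seg_start <- c(seg_start, t_now)
    seg_end <- c(seg_end, t_stop)
    seg_state <- rbind(seg_state, state)
    if (t_next >= horizon) break
    i <- sample.int(nv, 1, prob = rates)
    u <- parent_config_index(state[pidx[[i]]], cards[pidx[[i]]])
    row <- cims[[i]][[u]][state[i] + 1L, ]
    row[state[i] + 1L] <- 0
    state[i] <- sample.int(cards[i], 1, prob = row) - 1L
    t_now <- t_next
  }
  colnames(seg_state) <- vars
  out <- tibble::tibble(trajectory_id = 1L, t_start = seg_start, t_end = seg_end)
  out <- dplyr::bind_cols(out, tibble::as_tibble(seg_state))
  new_trajectory(out, vars)
}

#' Simulate several independent trajectories
#'
#' @param model A `ctbn_model` with CIMs.
#' @param n Number of trajectories.
#' @param horizon Duration in hours.
#' @param seed Integer seed; trajectory `i` uses a derived sub-seed.
#' @return A `ctbn_trajectory` tibble with `n` distinct `trajectory_id`s.
#' @export
sample_trajectories <- function(model, n, horizon = 72, seed = 1L) {
  seeds <- derive_seeds(seed, n)
  trajs <- purrr::map(seq_len(n), function(i) {
    tr <- sample_trajectory(model, horizon = horizon, seed = seeds[i])
    tr$trajectory_id <- i
    tr
  })
  new_trajectory(dplyr::bind_rows(trajs), model$variables)
}

new_trajectory <- function(tbl, variables) {
  structure(tbl, variables = variables,
            class = c("ctbn_trajectory", class(tibble::tibble())))
}

trajectory_variables <- function(traj) {
  attr(traj, "variables") %||%
    setdiff(names(traj), c("trajectory_id", "t_start", "t_end"))
}

#' Observe a trajectory on a sampling grid
#'
#' Reads off each variable's state at the given times with the
#' right-continuous convention: at an exact jump time the state *entered* at
#' that instant is reported.
#'
#' @param traj A single trajectory (`ctbn_trajectory` with one id).
#' @param grid Times in hours, within `[0, horizon]`.
#' @return A tibble with `time_h` and one state column per variable.
#' @export
observe_at_grid <- function(traj, grid) {
  stopifnot(length(grid) >= 1)
  if (length(unique(traj$trajectory_id)) != 1) {
    rlang::abort("observe_at_grid expects a single trajectory")
  }
  horizon <- max(traj$t_end)
  if (any(grid < min(traj$t_start) - 1e-9) || any(grid > horizon + 1e-9)) {
    rlang::abort("grid point outside the trajectory's time span")
  }
  vars <- trajectory_variables(traj)
  idx <- findInterval(grid, traj$t_start)  # last segment entered at or before t
  out <- tibble::tibble(time_h = grid)
  dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(traj)[idx, vars, drop = FALSE],
                                          .name_repair = "minimal"))
}

#' Emit a microarray-like expression bundle from observed states
#'
#' Builds probe intensities on the log2 scale: case expression is a per-gene
#' baseline plus the `level_map` center of the gene's current state plus
#' Gaussian noise; control expression is baseline plus noise. Null genes and
#' undetected probes carry baseline plus noise in both arms; undetected
#' probes additionally get detection p-values drawn from Uniform(0.5, 1)
#' (all other probes from Uniform(0, 0.01)).
#'
#' @param observations Long tibble with columns `gene`, `time_h`,
#'   `replicate`, `state` (0-based), e.g. from [observe_at_grid()] over
#'   replicates; see [simulate_bundle()] for the end-to-end path.
#' @param config A [generator_config()].
#' @param seed Integer seed for noise and detection p-values (defaults to
#'   `config$seed + 1`).
#' @return An `expression_bundle`: list with `values` (probe x sample log2
#'   matrix), `samples` metadata tibble (`sample_id`, `condition`, `time_h`,
#'   `replicate`), `detection_p` matrix, and `log2 = TRUE`.
#' @export
emit_expression <- function(observations, config, seed = config$seed + 1L) {
  cfg <- validate_generator_config(config)
  stopifnot(all(c("gene", "time_h", "replicate", "state") %in% names(observations)))
  if (any(observations$state < 0 | observations$state >= cfg$n_states)) {
    rlang::abort("observation state outside level_map range")
  }
  withr::local_seed(as.integer(seed))

  genes <- unique(observations$gene)
  null_genes <- if (cfg$n_null_genes > 0) sprintf("null%03d", seq_len(cfg$n_null_genes)) else character()
  und_probes <- if (cfg$n_undetected_probes > 0) sprintf("und%03d", seq_len(cfg$n_undetected_probes)) else character()
  probes <- c(genes, null_genes, und_probes)
  times <- sort(unique(observations$time_h))
  reps <- sort(unique(observations$replicate))

  samples <- tidyr::expand_grid(condition = c("case", "control"),
                                replicate = reps, time_h = times) |>
    dplyr::mutate(sample_id = sprintf("%s_t%g_r%d", .data$condition,
                                      .data$time_h, .data$replicate)) |>
    dplyr::select("sample_id", "condition", "time_h", "replicate")

  baseline <- stats::setNames(stats::runif(length(probes), 7, 9), probes)
  values <- matrix(0, nrow = length(probes), ncol = nrow(samples),
                   dimnames = list(probes, samples$sample_id))
  for (p in probes) values[p, ] <- baseline[[p]]

  state_lut <- observations |>
    dplyr::mutate(key = paste(.data$gene, .data$time_h, .data$replicate))
  signal <- stats::setNames(cfg$level_map[state_lut$state + 1L], state_lut$key)

  case_cols <- which(samples$condition == "case")
  for (j in case_cols) {
    keys <- paste(genes, samples$time_h[j], samples$replicate[j])
    missing <- keys[!keys %in% names(signal)]
    if (length(missing)) {
      rlang::abort(paste0("missing observation for ", missing[1]))
    }
    values[genes, j] <- values[genes, j] + unname(signal[keys])
  }
  if (cfg$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(length(values), 0, cfg$noise_sd),
                              nrow = nrow(values))
  }

  detection_p <- matrix(stats::runif(length(probes) * nrow(samples), 0, 0.01),
                        nrow = length(probes),
                        dimnames = dimnames(values))
  if (length(und_probes)) {
    detection_p[und_probes, ] <- stats::runif(length(und_probes) * nrow(samples),
                                              0.5, 1)
  }
  expression_bundle(values, samples, detection_p, log2 = TRUE)
}

#' Construct an expression bundle
#'
#' @param values Probe x sample numeric matrix (row and column names set).
#' @param samples Metadata tibble with `sample_id`, `condition` (`"case"` or
#'   `"control"`), `time_h`, `replicate`; must cover every column of `values`.
#' @param detection_p Optional probe x sample matrix of detection p-values.
#' @param log2 Logical: are `values` already on the log2 scale?
#' @return An `expression_bundle`.
#' @export
expression_bundle <- function(values, samples, detection_p = NULL, log2 = TRUE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "condition", "time_h", "replicate")
  if (!all(need %in% names(samples))) {
    rlang::abort(paste0("samples metadata needs columns: ", paste(need, collapse = ", ")))
  }
  if (!setequal(samples$sample_id, colnames(values))) {
    rlang::abort("samples metadata must cover every expression column exactly")
  }
  if (anyDuplicated(samples[c("condition", "time_h", "replicate")])) {
    rlang::abort("duplicate (condition, time, replicate) cell in metadata")
  }
  if (!all(samples$condition %in% c("case", "control"))) {
    rlang::abort('condition must be "case" or "control"')
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (!is.null(detection_p)) {
    stopifnot(all(dim(detection_p) == dim(values)))
    detection_p <- detection_p[rownames(values), colnames(values), drop = FALSE]
  }
  structure(list(values = values, samples = samples,
                 detection_p = detection_p, log2 = isTRUE(log2)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("<expression_bundle> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples (", if (x$log2) "log2" else "linear", " scale",
      if (!is.null(x$detection_p)) ", detection p present" else "", ")\n", sep = "")
  invisible(x)
}

#' Long-format view of an expression bundle
#'
#' @param x An `expression_bundle`.
#' @param ... Unused.
#' @return A tibble with `gene`, `sample_id`, `condition`, `time_h`,
#'   `replicate`, `value`.
#' @method tidy expression_bundle
#' @export
tidy.expression_bundle <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::select("gene", "sample_id", "condition", "time_h", "replicate", "value")
}

#' Simulate a full synthetic study
#'
#' End-to-end generator: draws a ground-truth CTBN, simulates one latent
#' trajectory per replicate, observes it on the sampling grid, and emits the
#' case/control expression bundle. The returned object carries everything a
#' validation run needs: the bundle, the model, the ground-truth discretized
#' states, and the true arc list.
#'
#' @param config A [generator_config()].
#' @return A `ctbn_simulation`: list with `bundle`, `model`, `states` (long
#'   tibble `gene`, `time_h`, `replicate`, `state`), `truth_arcs` (tibble
#'   `from`, `to`) and `config`.
#' @export
simulate_bundle <- function(config) {
  cfg <- validate_generator_config(config)
  model <- generate_model(cfg)
  seeds <- derive_seeds(cfg$seed + 1000L, cfg$n_replicates)
  states <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    traj <- sample_trajectory(model, horizon = cfg$horizon, seed = seeds[r])
    observe_at_grid(traj, cfg$grid) |>
      tidyr::pivot_longer(-"time_h", names_to = "gene", values_to = "state") |>
      dplyr::mutate(replicate = r)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("gene", "time_h", "replicate", "state")
  bundle <- emit_expression(states, cfg)
  structure(list(bundle = bundle, model = model, states = states,
                 truth_arcs = tidy.ctbn_model(model), config = cfg),
            class = "ctbn_simulation")
}

#' @export
print.ctbn_simulation <- function(x, ...) {
  cat("<ctbn_simulation> ", x$config$n_genes, " signal genes, ",
      nrow(x$truth_arcs), " true arcs, ", x$config$n_replicates,
      " replicates, ", length(x$config$grid), " time points\n", sep = "")
  invisible(x)
}

# One master seed, many independent derived streams (all < 2^31).
derive_seeds <- function(seed, n) {
  withr::local_seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Write a simulation to disk as plain-text tables
#'
#' Writes `expression.tsv`, `samples.tsv`, `detection_p.tsv`,
#' `truth_states.tsv` and `truth_network.sif` into `dir`.
#'
#' @param sim A `ctbn_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$bundle$values, file.path(dir, "expression.tsv"))
  utils::write.table(sim$bundle$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$bundle$detection_p)) {
    write_matrix_tsv(sim$bundle$detection_p, file.path(dir, "detection_p.tsv"))
  }
  utils::write.table(sim$states, file.path(dir, "truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sif(sim$truth_arcs, file.path(dir, "truth_network.sif"))
  invisible(dir)
}

write_matrix_tsv <- function(m, path, digits = 10) {
  df <- data.frame(probe = rownames(m), signif(m, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression bundle from plain-text tables
#'
#' @param expr_path TSV with a `probe` column then one column per sample.
#' @param samples_path TSV with `sample_id`, `condition`, `time_h`, `replicate`.
#' @param detection_p_path Optional TSV shaped like `expr_path`.
#' @param log2 Are the values on the log2 scale?
#' @return An `expression_bundle`.
#' @export
read_expression_bundle <- function(expr_path, samples_path,
                                   detection_p_path = NULL, log2 = TRUE) {
  read_m <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  values <- read_m(expr_path)
  samples <- tibble::as_tibble(utils::read.delim(samples_path))
  dp <- if (!is.null(detection_p_path)) read_m(detection_p_path) else NULL
  expression_bundle(values, samples, dp, log2 = log2)
}
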