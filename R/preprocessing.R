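#' Probe-selection and discretization settings
#'
#' Thresholds for the preprocessing chain: detection filtering, variability
#' filtering, per-time-point differential expression with
#' Benjamini-Hochberg correction, fold-change selection, and three-bin
#' discretization.
#'
#' @param detection_p_max Detection p-value threshold (probe counts as
#'   detected in a sample when p < this).
#' @param detection_min_frac Fraction of samples in which a probe must be
#'   detected to be retained.
#' @param literal_detection If `TRUE`, invert the filter and *discard* probes
#'   detected in at least `detection_min_frac` of samples (a literal reading
#'   of "probes with detection P values < 0.05 were discarded"; keeps only
#'   background probes, so the default is `FALSE`).
#' @param sd_min Probes with SD < `sd_min` over all samples are removed
#'   (strict inequality: SD exactly `sd_min` is retained).
#' @param de_alpha FDR threshold on BH-adjusted per-time-point p-values.
#' @param fc_abs_min A gene qualifies at a time point when its
#'   replicate-mean log2 fold change exceeds `fc_abs_min` in absolute value
#'   (strict: > 1 or < -1).
#' @param bin_edges Two increasing numbers; fold changes `<= bin_edges[1]`
#'   map to state 0, `>= bin_edges[2]` to state 2, the open interval between
#'   to state 1.
#' @param bh_scope `"per_time"` adjusts p-values within each time point
#'   (differential expression is computed per time point); `"global"`
#'   adjusts across all gene-time pairs at once.
#' @return A `selection_config` list.
#' @export
selection_config <- function(detection_p_max = 0.05,
                             detection_min_frac = 0.5,
                             literal_detection = FALSE,
                             sd_min = 0.15,
                             de_alpha = 0.05,
                             fc_abs_min = 1.0,
                             bin_edges = c(-1, 1),
                             bh_scope = c("per_time", "global")) {
  bh_scope <- match.arg(bh_scope)
  if (length(bin_edges) != 2 || diff(bin_edges) <= 0) {
    rlang::abort("bin_edges must be two strictly increasing numbers")
  }
  if (detection_p_max <= 0 || sd_min < 0 || de_alpha <= 0 || fc_abs_min < 0) {
    rlang::abort("selection thresholds must be positive")
  }
  structure(list(detection_p_max = detection_p_max,
                 detection_min_frac = detection_min_frac,
                 literal_detection = isTRUE(literal_detection),
                 sd_min = sd_min, de_alpha = de_alpha,
                 fc_abs_min = fc_abs_min, bin_edges = bin_edges,
                 bh_scope = bh_scope),
            class = "selection_config")
}

#' Log2-transform and normalize an expression bundle
#'
#' Linear-scale input is log2-transformed first (strictly positive values
#' required). `method = "quantile"` applies between-array quantile
#' normalization (via limma), `"median"` scales arrays to a common median,
#' `"none"` leaves the log2 values untouched, so the operation is idempotent
#' on already-normalized input.
#'
#' @param bundle An `expression_bundle`.
#' @param method One of `"quantile"`, `"median"`, `"none"`.
#' @return The bundle with `values` on the log2 scale, normalized.
#' @export
normalize_expression <- function(bundle, method = c("quantile", "median", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(bundle, "expression_bundle"))
  v <- bundle$values
  if (!bundle$log2) {
    bad <- rownames(v)[apply(v <= 0, 1, any)]
    if (length(bad)) {
      rlang::abort(c("non-positive linear intensities; cannot log2-transform",
                     utils::head(bad, 5)))
    }
    v <- log2(v)
  }
  v <- switch(method,
    none = v,
    quantile = {
      out <- limma::normalizeBetweenArrays(v, method = "quantile")
      dimnames(out) <- dimnames(v)
      out
    },
    median = {
      med <- apply(v, 2, stats::median)
      sweep(v, 2, med - mean(med))
    })
  bundle$values <- v
  bundle$log2 <- TRUE
  bundle
}

#' Filter probes by detection and variability
#'
#' Retains probes that (a) are detected — detection p-value below
#' `detection_p_max` in at least `detection_min_frac` of samples — and (b)
#' have a standard deviation of at least `sd_min` over all samples. Removal
#' counts per criterion are attached as the `"filter_counts"` attribute and
#' reported as a message.
#'
#' @param bundle An `expression_bundle`.
#' @param config A [selection_config()].
#' @return The filtered bundle.
#' @export
filter_probes <- function(bundle, config = selection_config()) {
  stopifnot(inherits(bundle, "expression_bundle"))
  v <- bundle$values
  keep_det <- rep(TRUE, nrow(v))
  if (!is.null(bundle$detection_p)) {
    frac_detected <- rowMeans(bundle$detection_p < config$detection_p_max)
    detected <- frac_detected >= config$detection_min_frac
    keep_det <- if (config$literal_detection) !detected else detected
  }
  sds <- apply(v, 1, stats::sd)
  keep_sd <- sds >= config$sd_min
  keep <- keep_det & keep_sd
  counts <- c(input = nrow(v),
              removed_detection = sum(!keep_det),
              removed_sd = sum(keep_det & !keep_sd),
              retained = sum(keep))
  if (!any(keep)) rlang::abort("all probes removed by filtering")
  message(sprintf("filter_probes: %d -> %d probes (%d failed detection, %d low SD)",
                  counts[["input"]], counts[["retained"]],
                  counts[["removed_detection"]], counts[["removed_sd"]]))
  bundle$values <- v[keep, , drop = FALSE]
  if (!is.null(bundle$detection_p)) {
    bundle$detection_p <- bundle$detection_p[keep, , drop = FALSE]
  }
  attr(bundle, "filter_counts") <- counts
  bundle
}

#' Per-replicate log2 fold changes against the control time course
#'
#' `FC(g, t, r) = case(g, t, r) - mean over control replicates of
#' control(g, t, .)`: each case replicate is referenced to the mean of the
#' control replicates at the matched time point.
#'
#' @param bundle A log2-scale `expression_bundle` with both conditions.
#' @return A tibble `gene`, `time_h`, `replicate`, `fc`.
#' @export
fold_change <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!bundle$log2) rlang::abort("fold_change needs log2-scale values (normalize first)")
  long <- tidy.expression_bundle(bundle)
  case_times <- unique(long$time_h[long$condition == "case"])
  ctrl_times <- unique(long$time_h[long$condition == "control"])
  missing <- setdiff(case_times, ctrl_times)
  if (length(missing)) {
    rlang::abort(paste0("no control samples at time(s): ",
                        paste(missing, collapse = ", ")))
  }
  ctrl_mean <- long |>
    dplyr::filter(.data$condition == "control") |>
    dplyr::summarise(ctrl = mean(.data$value), .by = c("gene", "time_h"))
  long |>
    dplyr::filter(.data$condition == "case") |>
    dplyr::left_join(ctrl_mean, by = c("gene", "time_h")) |>
    dplyr::mutate(fc = .data$value - .data$ctrl) |>
    dplyr::select("gene", "time_h", "replicate", "fc") |>
    dplyr::arrange(.data$gene, .data$time_h, .data$replicate)
}

#' Per-time-point differential expression (Welch t-test + BH)
#'
#' For each gene at each time point, a two-sample Welch t-test compares case
#' versus control replicates; p-values are Benjamini-Hochberg adjusted
#' within each time point (or globally, per `bh_scope`). When both groups
#' have zero variance the p-value is 1 if the group means agree and 0
#' otherwise.
#'
#' @param bundle A log2-scale `expression_bundle`.
#' @param config A [selection_config()] (for `bh_scope`).
#' @return A tibble `gene`, `time_h`, `p`, `q`.
#' @export
differential_expression <- function(bundle, config = selection_config()) {
  stopifnot(inherits(bundle, "expression_bundle"))
  long <- tidy.expression_bundle(bundle)
  n_rep <- long |>
    dplyr::summarise(n = dplyr::n(), .by = c("gene", "time_h", "condition"))
  if (any(n_rep$n < 2)) {
    rlang::abort("differential expression needs >= 2 replicates per condition per time point")
  }
  de <- long |>
    dplyr::summarise(
      p = welch_p(.data$value[.data$condition == "case"],
                  .data$value[.data$condition == "control"]),
      .by = c("gene", "time_h"))
  if (config$bh_scope == "per_time") {
    de <- de |> dplyr::mutate(q = stats::p.adjust(.data$p, "BH"), .by = "time_h")
  } else {
    de <- de |> dplyr::mutate(q = stats::p.adjust(.data$p, "BH"))
  }
  dplyr::arrange(de, .data$gene, .data$time_h)
}

welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Select differentially expressed, strongly changing genes
#'
#' Keeps genes for which, at one or more time points simultaneously, the
#' BH-adjusted p-value is below `de_alpha` *and* the replicate-mean log2
#' fold change exceeds `fc_abs_min` in absolute value (strictly).
#'
#' @param fc Fold-change tibble from [fold_change()].
#' @param de Differential-expression tibble from [differential_expression()].
#' @param config A [selection_config()].
#' @return A tibble of selected genes (`gene`, `n_sig_times`, `min_q`,
#'   `max_abs_fc`); zero rows (with a warning) when nothing passes.
#' @export
select_genes <- function(fc, de, config = selection_config()) {
  mean_fc <- fc |>
    dplyr::summarise(mfc = mean(.data$fc), .by = c("gene", "time_h"))
  joint <- dplyr::inner_join(mean_fc, de, by = c("gene", "time_h")) |>
    dplyr::mutate(hit = .data$q < config$de_alpha &
                    abs(.data$mfc) > config$fc_abs_min)
  sel <- joint |>
    dplyr::summarise(n_sig_times = sum(.data$hit),
                     min_q = min(.data$q),
                     max_abs_fc = max(abs(.data$mfc)),
                     .by = "gene") |>
    dplyr::filter(.data$n_sig_times > 0) |>
    dplyr::arrange(.data$gene)
  if (nrow(sel) == 0) warning("select_genes: no gene passed the selection rule")
  sel
}

#' Discretize fold changes into three states
#'
#' State 0 for `fc <= bin_edges[1]` (down), state 2 for `fc >= bin_edges[2]`
#' (up), state 1 between (unchanged). Both outer bins are closed, matching
#' fold-change bins at -1 and +1 where values of exactly -1 or 1 fall in the
#' outer bins.
#'
#' @param fc Fold-change tibble (`gene`, `time_h`, `replicate`, `fc`).
#' @param bin_edges Two increasing thresholds, default `c(-1, 1)`.
#' @return A tibble `gene`, `time_h`, `replicate`, `state` of class
#'   `ctbn_states`.
#' @export
discretize_fc <- function(fc, bin_edges = c(-1, 1)) {
  if (length(bin_edges) != 2 || diff(bin_edges) <= 0) {
    rlang::abort("bin_edges must be two strictly increasing numbers")
  }
  bad <- !is.finite(fc$fc)
  if (any(bad)) {
    b <- fc[bad, ][1, ]
    rlang::abort(sprintf("non-finite fold change for gene %s at %g h (replicate %s)",
                         b$gene, b$time_h, as.character(b$replicate)))
  }
  out <- fc |>
    dplyr::mutate(state = dplyr::case_when(
      .data$fc <= bin_edges[1] ~ 0L,
      .data$fc >= bin_edges[2] ~ 2L,
      TRUE ~ 1L)) |>
    dplyr::select("gene", "time_h", "replicate", "state")
  class(out) <- c("ctbn_states", class(tibble::tibble()))
  out
}

#' Drop genes with a constant discretized profile
#'
#' Removes genes whose state is identical at every time point in every
#' replicate; their trajectories carry no transitions and thus no
#' information for structure learning.
#'
#' @param states A `ctbn_states` tibble.
#' @return The tibble without constant genes; removed ids are messaged and
#'   attached as attribute `"dropped_genes"`.
#' @export
drop_constant_genes <- function(states) {
  per_gene <- states |>
    dplyr::summarise(constant = dplyr::n_distinct(.data$state) == 1, .by = "gene")
  dropped <- per_gene$gene[per_gene$constant]
  if (length(dropped) == nrow(per_gene)) {
    rlang::abort("all genes have constant discretized profiles")
  }
  if (length(dropped)) {
    message(sprintf("drop_constant_genes: removed %d constant gene(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", ")))
  }
  out <- dplyr::filter(states, !.data$gene %in% dropped)
  attr(out, "dropped_genes") <- dropped
  class(out) <- c("ctbn_states", class(tibble::tibble()))
  out
}

#' Run the full preprocessing chain
#'
#' normalize -> filter probes -> fold change -> differential expression ->
#' gene selection -> discretization -> constant-gene removal.
#'
#' @param bundle An `expression_bundle`.
#' @param config A [selection_config()].
#' @param normalize_method Passed to [normalize_expression()]. `"none"` is
#'   appropriate for data already on a comparable log2 scale (e.g. the
#'   synthetic generator's output); `"quantile"` for raw intensities.
#' @return A `preprocess_result`: list with `states` (selected, non-constant
#'   discretized genes), `fc`, `de`, `selected`, `filter_counts`,
#'   `dropped_genes` and `config`.
#' @export
preprocess_expression <- function(bundle, config = selection_config(),
                                  normalize_method = "none") {
  bundle <- normalize_expression(bundle, normalize_method)
  bundle <- filter_probes(bundle, config)
  fc <- fold_change(bundle)
  de <- differential_expression(bundle, config)
  selected <- select_genes(fc, de, config)
  fc_sel <- dplyr::filter(fc, .data$gene %in% selected$gene)
  if (nrow(fc_sel) == 0) rlang::abort("no genes selected; cannot discretize")
  states <- discretize_fc(fc_sel, config$bin_edges)
  states <- drop_constant_genes(states)
  structure(list(states = states, fc = fc, de = de, selected = selected,
                 filter_counts = attr(bundle, "filter_counts"),
                 dropped_genes = attr(states, "dropped_genes"),
                 config = config),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result> ", nrow(x$selected), " genes selected, ",
      dplyr::n_distinct(x$states$gene), " retained after constant-profile removal\n",
      sep = "")
  invisible(x)
}

#' One-row summary of a preprocessing run
#'
#' @param x A `preprocess_result`.
#' @param ... Unused.
#' @return A one-row tibble with probe/gene counts through each stage.
#' @method glance preprocess_result
#' @export
glance.preprocess_result <- function(x, ...) {
  fcounts <- x$filter_counts %||% c(input = NA, retained = NA)
  tibble::tibble(
    n_probes_input = unname(fcounts[["input"]]),
    n_probes_filtered = unname(fcounts[["retained"]]),
    n_genes_selected = nrow(x$selected),
    n_genes_constant = length(x$dropped_genes),
    n_genes_final = dplyr::n_distinct(x$states$gene))
}
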