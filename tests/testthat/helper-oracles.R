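# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Monte-Carlo integration of a family's likelihood over the Gamma/Dirichlet
# priors. Dwell intensities are sampled from their Gamma(alpha + 1, tau)
# prior; jump-distribution rows (3-state case, i.e. Beta(alpha, alpha)) use
# a proposal chosen for bounded importance weights: the prior itself when
# only one target state has counts, a uniform proposal when both do.
# Returns the estimate decomposed so callers can form the z statistic on the
# weight scale: (exp(log_closed - shift) - mean_w) / se_w.
mc_family_score <- function(Tm, M, alpha, tau, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  k <- nrow(Tm); C <- ncol(Tm)
  ll <- numeric(n_draws)
  for (u in seq_len(C)) for (x in seq_len(k)) {
    Mrow <- M[x, , u]; Mx <- sum(Mrow)
    q <- stats::rgamma(n_draws, shape = alpha + 1, rate = tau)
    ll <- ll + Mx * log(q) - q * Tm[x, u]
    if (k == 3) {
      oth <- setdiff(seq_len(k), x)
      m1 <- Mrow[oth[1]]; m2 <- Mrow[oth[2]]
      if (m1 > 0 && m2 > 0) {
        th <- stats::runif(n_draws)
        ll <- ll + (alpha + m1 - 1) * log(th) +
          (alpha + m2 - 1) * log1p(-th) - lbeta(alpha, alpha)
      } else if (m1 + m2 > 0) {
        th <- stats::rbeta(n_draws, alpha, alpha)
        tp <- if (m1 > 0) th else 1 - th
        ll <- ll + ifelse(tp > 0, max(m1, m2) * log(pmax(tp, 1e-300)), -Inf)
      }
    }
  }
  shift <- max(ll)
  w <- exp(ll - shift)
  list(shift = shift, mean_w = mean(w), se_w = stats::sd(w) / sqrt(n_draws))
}

# Random small-count sufficient statistics (k in 2:3, 1-2 parent configs).
random_small_stats <- function() {
  k <- sample(2:3, 1); C <- sample(1:2, 1)
  Tm <- matrix(round(stats::runif(k * C, 0, 5), 2), k, C)
  M <- array(0L, c(k, k, C))
  for (u in seq_len(C)) for (x in seq_len(k)) {
    tgt <- setdiff(seq_len(k), x)
    M[x, tgt, u] <- pmin(stats::rpois(length(tgt), 0.7), 3L)
  }
  structure(list(T = Tm, M = M, variable = "x", parents = character(),
                 cards = k), class = "ctbn_suffstats")
}

# Textbook Benjamini-Hochberg, written from the definition.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# A hand-built 2-state single-variable model with symmetric rate q.
two_state_model <- function(q) {
  cim <- matrix(c(-q, q, q, -q), 2, 2, byrow = TRUE)
  ctbn_model("x", 2L, cims = list(x = list(cim)))
}

# Manually assembled trajectory tibble (bypasses the simulator).
manual_trajectory <- function(t_start, t_end, states, id = 1L) {
  out <- tibble::tibble(trajectory_id = as.integer(id),
                        t_start = t_start, t_end = t_end)
  out <- dplyr::bind_cols(out, tibble::as_tibble(states))
  ctbnflow:::new_trajectory(out, names(states))
}

# Tiny hand-built expression bundle: values[gene, sample] built from a long
# spec tibble (gene, condition, time_h, replicate, value).
bundle_from_long <- function(long, detection_p = NULL) {
  long$sample_id <- sprintf("%s_t%g_r%d", long$condition, long$time_h, long$replicate)
  samples <- unique(long[c("sample_id", "condition", "time_h", "replicate")])
  genes <- unique(long$gene)
  values <- matrix(NA_real_, length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(long))) {
    values[long$gene[i], long$sample_id[i]] <- long$value[i]
  }
  expression_bundle(values, samples, detection_p, log2 = TRUE)
}
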