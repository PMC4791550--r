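test_that("normalization log2-transforms and is idempotent with method none", {
  vals <- matrix(c(8, 2, 4, 16), 2, 2,
                 dimnames = list(c("a", "b"), c("case_t0_r1", "control_t0_r1")))
  samples <- tibble::tibble(sample_id = colnames(vals),
                            condition = c("case", "control"),
                            time_h = 0, replicate = 1L)
  b <- expression_bundle(vals, samples, log2 = FALSE)
  n1 <- normalize_expression(b, "none")
  expect_equal(n1$values["a", "case_t0_r1"], 3)   # log2(8)
  expect_true(n1$log2)
  expect_identical(normalize_expression(n1, "none")$values, n1$values)
  # non-positive linear intensity is a domain error naming the probe
  vals2 <- vals; vals2["b", 1] <- -1
  b2 <- expression_bundle(vals2, samples, log2 = FALSE)
  expect_error(normalize_expression(b2, "none"), "b")
})

test_that("quantile normalization equalizes column distributions", {
  set.seed(1)
  base <- sort(stats::rnorm(50, 8, 1))
  vals <- cbind(a1 = sample(base), a2 = sample(base) + 3)  # global shift
  rownames(vals) <- sprintf("p%02d", 1:50)
  samples <- tibble::tibble(sample_id = c("a1", "a2"),
                            condition = c("case", "control"),
                            time_h = 0, replicate = 1L)
  b <- normalize_expression(expression_bundle(vals, samples, log2 = TRUE), "quantile")
  expect_equal(sort(b$values[, 1]), sort(b$values[, 2]), ignore_attr = TRUE)
  # identical value multisets are a fixed point up to reordering
  expect_equal(sort(b$values[, 1]), sort((vals[, 1] + (vals[, 1] + 3)) / 2),
               ignore_attr = TRUE)
})

test_that("probe filters follow the detection and SD rules", {
  set.seed(2)
  n_samp <- 8
  vals <- rbind(
    good  = stats::rnorm(n_samp, 8, 1),
    flat  = rep(8, n_samp) + seq(0, 0.1, length.out = n_samp) * 0.1, # SD ~ 0.003
    ghost = stats::rnorm(n_samp, 8, 1))
  colnames(vals) <- sprintf("case_t%d_r1", 1:n_samp)
  samples <- tibble::tibble(sample_id = colnames(vals), condition = "case",
                            time_h = 1:n_samp, replicate = 1L)
  dp <- matrix(0.001, 3, n_samp, dimnames = dimnames(vals))
  dp["ghost", ] <- 0.9
  b <- expression_bundle(vals, samples, dp)
  f <- suppressMessages(filter_probes(b))
  expect_identical(rownames(f$values), "good")
  counts <- attr(f, "filter_counts")
  expect_equal(unname(counts["removed_detection"]), 1L)
  expect_equal(unname(counts["removed_sd"]), 1L)
  # SD exactly at the threshold is retained (the removal rule is SD < 0.15)
  vals2 <- rbind(edge = c(rep(8 - 0.15, 4), rep(8 + 0.15, 4)))
  sd_edge <- stats::sd(vals2)
  vals2 <- 8 + (vals2 - 8) * (0.15 / sd_edge)  # SD exactly 0.15
  colnames(vals2) <- colnames(vals)
  b2 <- expression_bundle(vals2, samples, matrix(0.001, 1, n_samp, dimnames = dimnames(vals2)))
  expect_identical(rownames(suppressMessages(filter_probes(b2))$values), "edge")
  # literal reading discards the detected probes instead
  f_lit <- suppressMessages(
    filter_probes(b, selection_config(literal_detection = TRUE, sd_min = 0)))
  expect_identical(rownames(f_lit$values), "ghost")
  # removing everything is a hard error
  expect_error(suppressMessages(filter_probes(b, selection_config(sd_min = 99))),
               "all probes")
})

test_that("fold change references each case replicate to the control mean", {
  long <- tidyr::expand_grid(gene = c("g1", "g2"),
                             condition = c("case", "control"),
                             time_h = c(0, 24), replicate = 1:2)
  long$value <- 8
  b <- bundle_from_long(long)
  fc0 <- fold_change(b)
  expect_true(all(fc0$fc == 0))
  # +1 shift of case at one time point gives FC = 1 there
  long2 <- long
  long2$value[long2$condition == "case" & long2$time_h == 24] <- 9
  fc1 <- fold_change(bundle_from_long(long2))
  expect_true(all(fc1$fc[fc1$time_h == 24] == 1))
  expect_true(all(fc1$fc[fc1$time_h == 0] == 0))
  # unbalanced control replicates: mean of controls is the reference
  long3 <- long
  long3$value[long3$condition == "control" & long3$replicate == 1] <- 7
  fc3 <- fold_change(bundle_from_long(long3))
  expect_true(all(fc3$fc == 0.5))
  # missing control time point is an alignment error
  long4 <- long[!(long$condition == "control" & long$time_h == 24), ]
  expect_error(fold_change(bundle_from_long(long4)), "control")
})

test_that("differential expression handles degenerate groups and adjusts within time", {
  long <- tidyr::expand_grid(gene = c("g1", "g2"),
                             condition = c("case", "control"),
                             time_h = 0, replicate = 1:3)
  long$value <- 8
  long$value[long$gene == "g2" & long$condition == "case"] <- c(9.0, 9.1, 8.9)
  de <- differential_expression(bundle_from_long(long))
  expect_equal(de$p[de$gene == "g1"], 1)  # identical constant groups
  expect_lt(de$p[de$gene == "g2"], 0.01)
  # zero variance, unequal means: maximally significant by convention
  long$value[long$gene == "g2" & long$condition == "case"] <- 9
  de2 <- differential_expression(bundle_from_long(long))
  expect_equal(de2$p[de2$gene == "g2"], 0)
  # fewer than 2 replicates is an error
  expect_error(differential_expression(bundle_from_long(long[long$replicate == 1, ])),
               "replicates")
  # BH agrees with the manual computation on a known 5-gene table
  expect_equal(bh_brute_force(c(0.001, 0.01, 0.02, 0.8, 0.9)),
               c(0.005, 0.025, 0.02 * 5 / 3, 0.9, 0.9))
  expect_equal(stats::p.adjust(c(0.001, 0.01, 0.02, 0.8, 0.9), "BH"),
               c(0.005, 0.025, 0.02 * 5 / 3, 0.9, 0.9))
})

test_that("a strong synthetic signal is detected in nearly all runs", {
  hits <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    long <- tidyr::expand_grid(gene = sprintf("g%02d", 1:10),
                               condition = c("case", "control"),
                               time_h = 0, replicate = 1:3)
    long$value <- stats::rnorm(nrow(long), 8, 0.1)
    up <- long$gene == "g01" & long$condition == "case"
    long$value[up] <- long$value[up] + 2
    de <- differential_expression(bundle_from_long(long))
    de$q[de$gene == "g01"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("gene selection requires co-occurring significance and fold change", {
  fc <- tidyr::expand_grid(gene = c("a", "b", "c"), time_h = c(0, 24),
                           replicate = 1L)
  fc$fc <- c(0.1, 1.2,   # a: big FC at 24
             0.5, 0.5,   # b: never exceeds 1
             1.5, 1.5)   # c: big FC, poor q
  de <- tidyr::expand_grid(gene = c("a", "b", "c"), time_h = c(0, 24))
  de$p <- de$q <- c(0.5, 0.01, 0.001, 0.001, 0.2, 0.2)
  sel <- select_genes(fc, de)
  expect_identical(sel$gene, "a")
  # conjunction must hold at the same time point
  de2 <- de
  de2$q <- c(0.01, 0.5, 0.001, 0.001, 0.2, 0.2)  # a now significant only at t=0
  expect_warning(sel2 <- select_genes(fc, de2), "no gene")
  expect_equal(nrow(sel2), 0L)
})

test_that("discretization maps bin boundaries exactly as defined", {
  fc <- tibble::tibble(gene = "g", time_h = 1:5, replicate = 1L,
                       fc = c(-1, 1, 0, -1.0001, 0.9999))
  states <- discretize_fc(fc)
  expect_equal(states$state, c(0L, 2L, 1L, 0L, 1L))
  fc$fc[2] <- NaN
  expect_error(discretize_fc(fc), "g at 2")
})

test_that("constant discretized genes are dropped with exact accounting", {
  # 284 genes in, 26 constant, 258 out
  set.seed(4)
  grid <- tidyr::expand_grid(gene = sprintf("g%03d", 1:284), time_h = c(0, 24, 48),
                             replicate = 1:2)
  grid$state <- 1L
  varying <- sprintf("g%03d", 27:284)
  grid$state[grid$gene %in% varying & grid$time_h == 48] <- 2L
  out <- suppressMessages(drop_constant_genes(grid))
  expect_equal(dplyr::n_distinct(out$gene), 258L)
  expect_setequal(attr(out, "dropped_genes"), sprintf("g%03d", 1:26))
  # one state change in one replicate is enough to be retained
  g <- tidyr::expand_grid(gene = c("a", "b"), time_h = c(0, 24), replicate = 1:2)
  g$state <- 1L
  g$state[g$gene == "a" & g$time_h == 24 & g$replicate == 2] <- 2L
  out2 <- suppressMessages(drop_constant_genes(g))
  expect_identical(unique(out2$gene), "a")
  g$state <- 1L
  expect_error(suppressMessages(drop_constant_genes(g)), "all genes")
})

test_that("BH matches a brute-force reimplementation on random vectors", {
  set.seed(5)
  for (i in 1:25) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("pipeline composition preserves gene identity", {
  cfg <- generator_config(n_genes = 12, n_null_genes = 4, noise_sd = 0.2, seed = 18)
  sim <- simulate_bundle(cfg)
  prep <- suppressMessages(preprocess_expression(sim$bundle))
  input_genes <- rownames(sim$bundle$values)
  expect_true(all(prep$selected$gene %in% input_genes))
  expect_true(all(unique(prep$states$gene) %in% prep$selected$gene))
})
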