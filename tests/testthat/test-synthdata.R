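test_that("gen_expression is deterministic and shape-conserving", {
  cfg <- sim_config(n_genes = 300, n_tf_genes = 40, n_planted = 5,
                    n_histone = 4, seed = 7)
  a <- gen_expression(cfg)
  b <- gen_expression(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$source), c(300, cfg$reps_per_group))
  expect_equal(dim(a$target), c(300, cfg$reps_per_group))
  expect_equal(sum(a$annotation$is_dna_binding), 40)
  expect_equal(sum(a$annotation$is_histone), 4)
  expect_true(all(a$truth$planted_genes %in%
                    a$annotation$gene_id[a$annotation$is_dna_binding]))
})

test_that("no planted effect leaves per-gene differences centred at zero", {
  cfg <- sim_config(n_genes = 500, n_tf_genes = 50, n_planted = 5,
                    planted_log2fc = 0, n_decoy = 0, n_histone = 0,
                    noise_sd = 0.3, seed = 13)
  sim <- gen_expression(cfg)
  diffs <- rowMeans(sim$target$values) - rowMeans(sim$source$values)
  bound <- 3 * cfg$noise_sd / sqrt(cfg$n_genes * cfg$reps_per_group)
  expect_lt(abs(mean(diffs)), bound)
})

test_that("planted genes are recoverable by the per-gene mean difference", {
  cfg <- sim_config(n_genes = 1000, n_tf_genes = 80, n_planted = 50,
                    planted_log2fc = 2, n_decoy = 0, noise_sd = 0.3,
                    reps_per_group = 4, seed = 1)
  sim <- gen_expression(cfg)
  de <- compute_de(sim$source, sim$target)
  # brute-force per-gene mean difference, independently of compute_de
  diffs <- rowMeans(sim$target$values) - rowMeans(sim$source$values)
  expect_equal(de$log2fc, unname(diffs))
  recovered <- de$gene_id[de$log2fc >= 1]
  expect_true(all(sim$truth$planted_genes %in% recovered))
})

test_that("non-planted mean differences are statistically calibrated", {
  means <- vapply(1:100, function(s) {
    cfg <- sim_config(n_genes = 100, n_tf_genes = 20, n_planted = 3,
                      n_decoy = 0, n_histone = 0, reps_per_group = 2,
                      noise_sd = 0.4, seed = s)
    sim <- gen_expression(cfg)
    non <- setdiff(sim$annotation$gene_id, sim$truth$planted_genes)
    idx <- match(non, gene_ids(sim$source))
    mean(rowMeans(sim$target$values[idx, ]) - rowMeans(sim$source$values[idx, ]))
  }, numeric(1))
  # per-seed mean of 97 null diffs, each diff has sd noise_sd * sqrt(2/reps)
  se <- 0.4 * sqrt(2 / 2) / sqrt(97 * 100)
  expect_lt(abs(mean(means)), 4 * se)
})

test_that("gen_network respects planted edges and the background rate", {
  cfg <- sim_config(n_genes = 50, n_tf_genes = 10, n_planted = 4, n_decoy = 2,
                    n_modifiers = 3, seed = 2)
  sim <- gen_expression(cfg)
  planted <- rbind(sim$truth$planted_internal_edges,
                   sim$truth$planted_modifier_edges)

  net0 <- gen_network(sim$annotation, sim$truth, p_background = 0, seed = 5)
  expect_equal(nrow(net0$edges), nrow(unique(planted)))

  # complete background on 4 nodes: all 6 pairs present
  ann4 <- data.frame(gene_id = c("a", "b", "c", "d"), symbol = c("a", "b", "c", "d"),
                     is_dna_binding = TRUE, is_histone = FALSE)
  truth0 <- list(planted_internal_edges = data.frame(from = character(0), to = character(0)),
                 planted_modifier_edges = data.frame(from = character(0), to = character(0)),
                 modifier_genes = character(0))
  net1 <- gen_network(ann4, truth0, p_background = 1, seed = 1)
  expect_equal(nrow(net1$edges), 6)

  # binomial expectation on 500 nodes at p = 0.01
  ann500 <- data.frame(gene_id = sprintf("n%03d", 1:500), symbol = sprintf("n%03d", 1:500),
                       is_dna_binding = FALSE, is_histone = FALSE)
  net2 <- gen_network(ann500, truth0, p_background = 0.01, seed = 3)
  expected <- 0.01 * choose(500, 2)
  expect_lt(abs(nrow(net2$edges) - expected), 4 * sqrt(expected))
})

test_that("generated networks are always simple graphs", {
  for (s in 1:10) {
    cfg <- sim_config(n_genes = 60, n_tf_genes = 15, n_planted = 5, n_decoy = 3,
                      n_modifiers = 4, seed = s)
    sim <- gen_expression(cfg)
    net <- gen_network(sim$annotation, sim$truth, p_background = 0.05, seed = s)
    expect_true(all(net$edges$from != net$edges$to))
    keys <- paste(pmin(net$edges$from, net$edges$to),
                  pmax(net$edges$from, net$edges$to))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("gen_survival follows the exponential decay model", {
  exact <- gen_survival(1, 100, c(0, 1, 2), noise_sd = 0, seed = 1)
  expect_equal(exact$count, c(100, 50, 25))

  s <- gen_survival(7.1, 1000, c(0.5, 2, 6, 12, 24), noise_sd = 0.05, seed = 11)
  fit <- fit_half_life(s)
  expect_lt(abs(fit$half_life - 7.1), 0.5)

  expect_identical(gen_survival(5, 10, c(0, 1, 2), 0.1, seed = 4),
                   gen_survival(5, 10, c(0, 1, 2), 0.1, seed = 4))
  expect_error(gen_survival(-1, 10, c(0, 1, 2)), "half_life")
  expect_error(gen_survival(1, 0, c(0, 1, 2)), "n0")
})

test_that("gen_cytometry conserves events and matches class probabilities", {
  one <- gen_cytometry(100, c(A = 1.0), seed = 1)
  expect_equal(one$count, 100)

  for (s in 1:5) {
    tab <- gen_cytometry(1234, c(a = 0.2, b = 0.5, c = 0.3), seed = s)
    expect_equal(sum(tab$count), 1234)
  }

  big <- gen_cytometry(1e5, c(pos = 0.3, neg = 0.7), seed = 5)
  expect_lt(abs(big$count[big$label == "pos"] / 1e5 - 0.3), 0.01)

  expect_error(gen_cytometry(10, c(a = 0.5, b = 0.6)), "sum to 1")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_planted = 30, n_decoy = 0, n_tf_genes = 20),
               "n_planted")
  expect_error(sim_config(n_tf_genes = 1999, n_histone = 10, n_genes = 2000),
               "n_histone")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(reps_per_group = 1), "reps_per_group")
})
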