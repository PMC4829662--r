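test_that("informative-probe filtering keeps genes detected in any sample", {
  dp <- rbind(rep(0.001, 3),            # detected everywhere
              rep(0.5, 3),              # detected nowhere
              c(0.5, 0.5, 0.005))       # detected in one sample
  m <- make_expr(rnorm(9), genes = c("ga", "gb", "gc"), detection_p = dp)
  out <- filter_informative(m)
  expect_equal(gene_ids(out), c("ga", "gc"))

  all_good <- make_expr(rnorm(9), genes = c("ga", "gb", "gc"),
                        detection_p = matrix(0.001, 3, 3))
  expect_equal(dim(filter_informative(all_good)), c(3, 3))

  no_dp <- make_expr(rnorm(9), genes = c("ga", "gb", "gc"))
  expect_error(filter_informative(no_dp), "detection")
})

test_that("quantile normalization equalizes sample distributions", {
  m <- make_expr(c(1, 2, 3, 4, 5, 6))
  out <- normalize_expression(m)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))

  single <- make_expr(c(3, 1, 2))
  expect_equal(normalize_expression(single)$values, single$values)

  expect_error(normalize_expression(make_expr(c(-1, 2, 3, 4, 5, 6)),
                                    linear_scale = TRUE), "positive")
})

test_that("welch test matches stats::t.test gene by gene", {
  set.seed(21)
  a <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("g", 1:5), paste0("a", 1:8)))
  b <- matrix(rnorm(30, 0.5), 5, 6, dimnames = list(paste0("g", 1:5), paste0("b", 1:6)))
  de <- differential_expression(a, b)
  for (i in 1:5) {
    ref <- t.test(b[i, ], a[i, ])
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("reported FDR equals the Benjamini-Hochberg step-up oracle", {
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # and through the user-facing path
  a <- matrix(rnorm(200), 25, 8, dimnames = list(sprintf("g%02d", 1:25), paste0("a", 1:8)))
  b <- a + matrix(rnorm(200, 0, 0.5), 25, 8)
  colnames(b) <- paste0("b", 1:8)
  de <- differential_expression(a, b)
  expect_equal(de$fdr, bh_oracle(de$p_value), tolerance = 1e-12)
})

test_that("identical groups yield no significant genes", {
  set.seed(1)
  m <- matrix(rnorm(400), 50, 8, dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  de <- differential_expression(m[, 1:4], m[, 5:8])
  expect_equal(de, transform(de, significant = FALSE))
  same <- differential_expression(m[, 1:4], m[, 1:4])
  expect_false(any(same$significant))
  expect_true(all(same$p_value == 1))
})

test_that("null simulation stays near the nominal false-positive budget", {
  set.seed(2)
  m <- matrix(rnorm(8000), 1000, 8,
              dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:8)))
  de <- differential_expression(m[, 1:4], m[, 5:8])
  expect_lte(sum(de$significant), 3)
})

test_that("planted two-fold effects are recovered with high power", {
  set.seed(9)
  n <- 1000
  base <- matrix(rnorm(n * 8, 8, 0.25), n, 8,
                 dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:8)))
  planted <- sample(n, 50)
  base[planted, 5:8] <- base[planted, 5:8] + 2
  de <- differential_expression(base[, 1:4], base[, 5:8])
  expect_gte(sum(de$significant[planted]), 48)
})

test_that("UPGMA on correlation distance matches the naive oracle", {
  set.seed(14)
  for (i in 1:10) {
    ns <- sample(4:8, 1)
    m <- matrix(rnorm(ns * 30), 30, ns,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:ns)))
    hc <- hierarchical_cluster(m)
    D <- 1 - cor(m)
    expect_equal(sort(hc$height), sort(upgma_heights_oracle(D)),
                 tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("a duplicated sample merges first at height zero", {
  set.seed(8)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10),
                                                c("s1", "s2", "s3", "s4")))
  m <- cbind(m, s5 = m[, "s2"])
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("s2", "s5"))

  flat <- m; flat[, 1] <- 5
  expect_error(hierarchical_cluster(flat), "zero-variance")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  uni <- sprintf("u%02d", 1:10)
  sig <- uni[1:4]
  sets <- list(hit = uni[c(1:3, 5, 6)], all = uni, none = uni[8:10])
  res <- hypergeom_enrich(sig, uni, sets)
  expect_equal(res$p_value[res$term == "all"], 1)
  expect_equal(res$p_value[res$term == "none"], 1)  # k = 0: upper tail from 0
  # N=10, K=5, n=4, k=3 by enumeration
  expect_equal(res$p_value[res$term == "hit"], hyper_tail_oracle(3, 5, 10, 4),
               tolerance = 1e-12)

  # the worked k = 4 case: p = C(5,4)/C(10,4) = 5/210
  res4 <- hypergeom_enrich(uni[1:4], uni, list(s = uni[1:5]))
  expect_equal(res4$p_value, 5 / 210 + hyper_tail_oracle(5, 5, 10, 4),
               tolerance = 1e-12)
  expect_equal(res4$p_value, hyper_tail_oracle(4, 5, 10, 4), tolerance = 1e-12)

  set.seed(6)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    uni <- sprintf("x%02d", seq_len(N))
    sig <- sample(uni, sample(1:N, 1))
    term <- sample(uni, sample(1:N, 1))
    res <- hypergeom_enrich(sig, uni, list(t = term))
    expect_equal(res$p_value,
                 hyper_tail_oracle(length(intersect(term, sig)),
                                   length(term), N, length(sig)),
                 tolerance = 1e-12)
  }
})

test_that("running-sum enrichment score matches the naive oracle", {
  # whole ranking in the set
  s <- setNames(c(4, 3, 2, 1, 0.5), paste0("gene", 1:5))
  expect_equal(gsea(s, names(s), n_perm = 10)$es, 1)

  # single top hit, unweighted
  expect_equal(gsea(s, "gene1", n_perm = 10, weight_p = 0)$es, 1)

  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    sc <- setNames(round(rnorm(n), 2), sprintf("g%02d", seq_len(n)))
    sc <- sc + seq(n, 1) * 1e-3       # avoid exact ties
    set <- sample(names(sc), sample(1:(n - 1), 1))
    wp <- sample(c(0, 1, 1.5), 1)
    res <- gsea(sc, set, n_perm = 10, weight_p = wp)
    ord <- order(sc, decreasing = TRUE)
    expect_equal(res$es, es_oracle(sc[ord], names(sc)[ord] %in% set, wp),
                 tolerance = 1e-12)
  }

  expect_error(gsea(s, "absent", n_perm = 10), "disjoint")
  expect_error(gsea(s, "gene1", n_perm = 5), "n_perm")
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:10) {
    n <- 50
    sc <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%02d", 1:n))
    set <- sample(names(sc), 8)
    mine <- gsea(sc, set, n_perm = 10, weight_p = 1)$es
    ref <- fgsea::calcGseaStat(unname(sc), selectedStats = which(names(sc) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("a planted top-quartile set is detected by permutation GSEA", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    sc <- setNames(sort(rnorm(n, 0, 1), decreasing = TRUE), sprintf("g%03d", 1:n))
    set <- sample(names(sc)[1:125], 30)   # top quartile
    res <- gsea(sc, set, n_perm = 1000, weight_p = 1, seed = s)
    res$nes > 0 && res$fdr < 0.25
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("principal coordinates reproduce embeddable distances", {
  # 3-4-5 right triangle
  d <- dist(rbind(c(0, 0), c(3, 0), c(3, 4)))
  res <- pcoa(d, n_components = 2)
  expect_equal(sort(as.vector(dist(res$coordinates))), c(3, 4, 5),
               tolerance = 1e-9)

  set.seed(31)
  for (i in 1:10) {
    np <- sample(4:10, 1)
    pts <- matrix(rnorm(np * 3), np, 3)
    res <- pcoa(dist(pts), n_components = np - 1)
    expect_lt(norm(as.matrix(dist(res$coordinates)) - as.matrix(dist(pts)), "F"),
              1e-8)
    expect_true(all(abs(colSums(res$coordinates)) < 1e-8))
    expect_true(all(diff(res$variance_fraction) <= 1e-12))
  }

  m <- make_expr(rnorm(30), genes = sprintf("g%02d", 1:6),
                 samples = sprintf("s%d", 1:5))
  m$values[, 2] <- m$values[, 1]
  res <- pcoa(m, n_components = 2)
  expect_equal(res$coordinates[1, ], res$coordinates[2, ], tolerance = 1e-9)

  expect_error(pcoa(dist(rbind(c(0, 0), c(1, 0))), n_components = 3), "samples")
})

test_that("overlap counting partitions the union exactly", {
  res <- de_overlap(list(A = c("1", "2", "3"), B = c("3", "4")))
  expect_equal(res$common, 1)
  expect_equal(res$total, 4)
  regions <- setNames(res$regions$count, res$regions$region)
  expect_equal(regions[["A"]], 2)
  expect_equal(regions[["B"]], 1)
  expect_equal(regions[["A&B"]], 1)

  same <- de_overlap(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(same$common, 5)
  expect_equal(same$total, 5)
  expect_equal(sum(res$regions$count), res$total)
})

test_that("GMT files round-trip including one-member sets", {
  sets <- list(big = sprintf("g%02d", 1:10),
               tiny = "g99")
  attr(sets$big, "description") <- "a big set"
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(names(back), c("big", "tiny"))
  expect_equal(as.character(back$big), as.character(sets$big))
  expect_equal(as.character(back$tiny), "g99")
  expect_equal(attr(back$big, "description"), "a big set")
})
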