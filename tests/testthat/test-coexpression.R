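test_that("correlation matrix matches a hand Pearson computation", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 1, 4, 3), g3 = c(5, 5, 4, 1))
  colnames(x) <- paste0("s", 1:4)
  cc <- correlation_matrix(make_expr(x))
  hand <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  expect_equal(cc["g1", "g2"], hand(x[1, ], x[2, ]), tolerance = 1e-12)
  expect_equal(cc["g1", "g3"], hand(x[1, ], x[3, ]), tolerance = 1e-12)
  expect_equal(cc["g2", "g3"], hand(x[2, ], x[3, ]), tolerance = 1e-12)
  expect_equal(diag(cc), c(g1 = 1, g2 = 1, g3 = 1))
  expect_lt(max(abs(cc - t(cc))), 1e-12)
})

test_that("correlation edge cases: duplicates, negation, zero variance", {
  x <- rbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), c = -c(1, 2, 3, 5),
             d = rep(2, 4))
  colnames(x) <- paste0("s", 1:4)
  expect_warning(cc <- correlation_matrix(make_expr(x)), "zero-variance")
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_equal(unname(cc["d", c("a", "b", "c")]), c(0, 0, 0))
  expect_equal(cc["d", "d"], 1)
})

test_that("adjacency follows the unsigned and signed soft-threshold forms", {
  cc <- matrix(c(1, 0.5, 0, 0.5, 1, -0.5, 0, -0.5, 1), 3, 3)
  a1 <- adjacency(cc, network_params(power = 1))
  expect_equal(a1[1, 2], 0.5)
  expect_equal(a1[1, 3], 0)
  a6 <- adjacency(cc, network_params(power = 6))
  expect_equal(a6[1, 2], 0.5^6)        # 0.015625
  expect_equal(a6[2, 3], 0.5^6)        # unsigned: |cor|
  s2 <- adjacency(cc, network_params(power = 2, signed = TRUE))
  expect_equal(s2[2, 3], ((1 - 0.5) / 2)^2)
  expect_equal(diag(a6), rep(1, 3))
})

test_that("TOM matches the formula by hand and by triple-loop oracle", {
  adj <- matrix(c(1, 0.8, 0.4,
                  0.8, 1, 0.2,
                  0.4, 0.2, 1), 3, 3)
  tom <- topological_overlap(adj)
  # hand: TOM_12 = (a13*a32 + a12) / (min(k1,k2) + 1 - a12)
  expect_equal(tom[1, 2], (0.4 * 0.2 + 0.8) / (min(1.2, 1.0) + 1 - 0.8),
               tolerance = 1e-12)
  # saturation / empty-graph limits
  ones <- matrix(1, 4, 4)
  expect_equal(topological_overlap(ones), ones)
  eye <- diag(4)
  expect_equal(topological_overlap(eye), eye)
  # brute-force triple loop on random 6-node networks
  tom_brute <- function(a) {
    n <- nrow(a)
    out <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
    }
    out
  }
  set.seed(1)
  for (rep in 1:20) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2; diag(a) <- 1
    expect_lt(max(abs(topological_overlap(a) - tom_brute(a))), 1e-12)
  }
})

test_that("soft-threshold selection finds scale-free fits and falls back", {
  set.seed(2)
  # heavy-tailed factor loadings give a broad connectivity distribution
  n <- 150; ns <- 300
  load <- runif(n)^(-1 / 2.5); load <- pmin(load / max(load), 0.95)
  x <- outer(load, rnorm(ns)) + matrix(rnorm(n * ns), n, ns) * sqrt(1 - load^2)
  dimnames(x) <- list(sprintf("g%03d", 1:n), sprintf("s%03d", 1:ns))
  cc <- correlation_matrix(make_expr(x))
  pw <- pick_soft_threshold(cc)
  expect_gte(max(attr(pw, "rsq"), na.rm = TRUE), 0.8)
  expect_false(attr(pw, "fallback"))
  expect_identical(as.numeric(pick_soft_threshold(cc)), as.numeric(pw))
  # all-equal correlations -> no scale-free fit, fallback power 6
  flat <- matrix(0.5, 20, 20); diag(flat) <- 1
  expect_warning(pw6 <- pick_soft_threshold(flat), "falling back")
  expect_equal(as.numeric(pw6), 6)
  expect_error(pick_soft_threshold(diag(10)), "degenerate")
})

test_that("module detection recovers planted blocks and leaves noise grey", {
  cfg <- simulation_config(
    n_genes = 150,
    module_specs = list(module_spec("b1", 30, "up", 0.7, 1),
                        module_spec("b2", 25, "up", 0.7, 1)),
    n_reference_1 = 200, seed = 4)
  ref <- simulate_reference_cohort(cfg, 1)
  blocks <- planted_modules(cfg)
  assign <- detect_modules(ref, genes(ref), network_params(),
                           dataset_tag = "ref1", direction_tag = "up")
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  found <- setdiff(unique(assign$module), "grey")
  expect_length(found, 2L)
  j <- vapply(blocks, function(b)
    max(vapply(found, function(m) jacc(module_genes(assign, m), b), 1)), 1)
  expect_true(all(j >= 0.8))
  # labels ordered by decreasing size
  expect_gte(length(module_genes(assign, "M1")),
             length(module_genes(assign, "M2")))
  # pure noise: no module called in >= 9/10 replicates
  all_grey <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(50 * 200), 50, 200,
                dimnames = list(sprintf("n%02d", 1:50), sprintf("s%03d", 1:200)))
    a <- suppressWarnings(detect_modules(make_expr(x), rownames(x)))
    all(a$module == "grey")
  }, TRUE)
  expect_gte(mean(all_grey), 0.9)
})

test_that("module partition is invariant to gene input order", {
  cfg <- simulation_config(
    n_genes = 80,
    module_specs = list(module_spec("b1", 20, "up", 0.7, 1)),
    n_reference_1 = 150, seed = 6)
  ref <- simulate_reference_cohort(cfg, 1)
  a1 <- detect_modules(ref, genes(ref))
  set.seed(1)
  perm <- sample(genes(ref))
  a2 <- detect_modules(ref, perm)
  m1 <- setNames(a1$module, a1$gene)
  m2 <- setNames(a2$module, a2$gene)[names(m1)]
  # same partition up to label names
  expect_equal(unname(m1 == "grey"), unname(m2 == "grey"))
  for (m in setdiff(unique(m1), "grey"))
    expect_equal(length(unique(m2[m1 == m])), 1L)
  # fewer genes than min size -> single grey assignment with warning
  expect_warning(a3 <- detect_modules(ref, genes(ref)[1:5]), "min_module_size")
  expect_true(all(a3$module == "grey"))
})

test_that("higher planted correlation gives non-decreasing recovery", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  rec <- vapply(c(0.4, 0.6, 0.8), function(rho) {
    cfg <- simulation_config(
      n_genes = 100,
      module_specs = list(module_spec("b1", 25, "up", rho, 1)),
      n_reference_1 = 200, seed = 8)
    ref <- simulate_reference_cohort(cfg, 1)
    a <- suppressWarnings(detect_modules(ref, genes(ref)))
    found <- setdiff(unique(a$module), "grey")
    if (!length(found)) return(0)
    max(vapply(found, function(m)
      jacc(module_genes(a, m), planted_modules(cfg)$b1), 1))
  }, 1)
  expect_true(all(diff(rec) >= 0))
  expect_gte(rec[3], 0.8)
})
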