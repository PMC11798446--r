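test_that("quantile normalization matches the hand-computed example", {
  m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
  rownames(m) <- c("p1", "p2")
  out <- preprocess_expression(m)
  # row-wise sorted means: (mean(1,3), mean(2,4)) = (2, 3) in both columns
  expect_equal(unname(out[, 1]), c(2, 3))
  expect_equal(unname(out[, 2]), c(2, 3))
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  set.seed(1)
  m <- matrix(rnorm(200, 8, 2), nrow = 40,
              dimnames = list(paste0("p", 1:40), paste0("s", 1:5)))
  once <- preprocess_expression(m)
  twice <- preprocess_expression(once)
  expect_equal(twice, once, tolerance = 1e-12)
  sorted <- apply(once, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  # identical columns are a fixed point
  ident <- matrix(rep(c(5, 6, 7), 4), ncol = 4,
                  dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  expect_equal(preprocess_expression(ident), ident)
})

test_that("linear-scale input is detected and log2-transformed", {
  m <- matrix(c(1023, 255, 511, 127), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out <- preprocess_expression(m)
  expect_lt(max(out), 11)
  m_log <- matrix(c(8, 4, 9, 5), nrow = 2,
                  dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_equal(max(preprocess_expression(m_log)), 8.5)
  expect_error(preprocess_expression(matrix(c("a", "b"), ncol = 1)),
               "non-numeric")
})

test_that("moderated t matches the fixed-hyperparameter worked example", {
  m <- rbind(g1 = c(0, 2, 3, 5))
  colnames(m) <- paste0("s", 1:4)
  fit <- moderated_t_test(m, groups = c("case", "case", "control", "control"),
                          prior = list(d0 = 4, s0_sq = 1))
  tb <- tidy(fit)
  # s_g^2 = 2, shrunken variance (4*1 + 2*2)/6 = 4/3, t = -3/sqrt(4/3 * 1)
  expect_equal(tb$log2fc, -3)
  expect_equal(abs(tb$t_mod), 2.598, tolerance = 1e-3)
  expect_equal(tb$df_total, 6)
  expect_equal(tb$p, 2 * pt(-2.598076, df = 6), tolerance = 1e-5)
})

test_that("moderated t limits: equal means, d0 -> 0 and d0 -> Inf", {
  set.seed(2)
  m <- matrix(rnorm(400, 5), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:20)))
  groups <- rep(c("case", "control"), each = 10)
  m["g1", ] <- rep(c(1, 2, 3, 4, 5), 4) # identical pattern in both groups
  fit0 <- moderated_t_test(m, groups, prior = list(d0 = 1e-12, s0_sq = 1))
  ordinary <- apply(m, 1, function(x) {
    t.test(x[groups == "case"], x[groups == "control"],
           var.equal = TRUE)$statistic
  })
  expect_equal(tidy(fit0)$t_mod, unname(ordinary), tolerance = 1e-6)
  expect_equal(tidy(fit0)$t_mod[1], 0)
  expect_equal(tidy(fit0)$p[1], 1)
  fit_inf <- moderated_t_test(m, groups, prior = list(d0 = Inf, s0_sq = 2))
  fc <- tidy(fit_inf)$log2fc
  expect_equal(tidy(fit_inf)$t_mod, fc / sqrt(2 * (1 / 10 + 1 / 10)),
               tolerance = 1e-12)
})

test_that("estimated-hyperparameter path agrees with the limma oracle", {
  set.seed(3)
  m <- matrix(rnorm(3000, 7, 1.5), nrow = 150,
              dimnames = list(paste0("g", 1:150), paste0("s", 1:20)))
  groups <- rep(c("case", "control"), each = 10)
  m[1:10, groups == "case"] <- m[1:10, groups == "case"] + 2
  fit <- moderated_t_test(m, groups)
  design <- cbind(Intercept = 1, case = as.numeric(groups == "case"))
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(glance(fit)$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(glance(fit)$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(tidy(fit)$t_mod, unname(lfit$t[, "case"]), tolerance = 1e-8)
  expect_equal(tidy(fit)$p, unname(lfit$p.value[, "case"]), tolerance = 1e-8)
  expect_error(moderated_t_test(matrix(5, 3, 4,
                                       dimnames = list(letters[1:3], NULL)),
                                groups = c("case", "case", "control", "control")),
               "zero within-group variance")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in ranks
})

test_that("probe collapsing keeps the minimum-adj-p probe with documented ties", {
  res <- tibble::tibble(
    probe = c("pA", "pB", "pC", "pD", "pE", "pF"),
    log2fc = c(1, 2, 3, 4, 5, 6),
    t_mod = 1, df_total = 10, p = 0.01,
    adj_p = c(0.02, 0.001, 0.05, 0.05, 0.03, 0.01))
  ann <- tibble::tibble(probe = res$probe,
                        symbol = c("G1", "G1", "G2", "G2", "", "g3"))
  out <- collapse_probes(res, ann)
  expect_identical(out$probe[out$gene == "G1"], "pB")   # min adj_p wins
  expect_identical(out$probe[out$gene == "G2"], "pC")   # tie: lexicographic
  expect_false("pE" %in% out$probe)                     # blank dropped
  expect_identical(out$gene[out$probe == "pF"], "G3")   # case-folded
})

test_that("DEG thresholds are inclusive on |log2FC| and strict on adj p", {
  rec <- tibble::tibble(gene = c("A", "B", "C", "D", "E"),
                        log2fc = c(1.3, -1.5, 1.19, 1.2, 2.0),
                        adj_p = c(0.005, 0.009, 0.001, 0.01, 0.02))
  out <- filter_degs(rec)
  expect_identical(out$gene, c("A", "B"))
  expect_identical(out$direction, c("up", "down"))
})

test_that("null data yields about the nominal false-positive rate", {
  set.seed(5)
  fracs <- replicate(20, {
    m <- matrix(rnorm(2000 * 12, 6, 1), nrow = 2000)
    rownames(m) <- paste0("g", 1:2000)
    fit <- moderated_t_test(m, groups = rep(c("case", "control"), each = 6))
    mean(tidy(fit)$adj_p < 0.01)
  })
  expect_lte(mean(fracs), 0.01)
})

test_that("planted strong effects are recovered as DEGs", {
  for (seed in 1:5) {
    cfg <- synth_config(universe_size = 80, shared_core_size = 60,
                        samples_per_group = 30, seed = seed)
    tb <- run_deg(generate_expression_dataset(cfg, 1, 1))
    degs <- tb$gene[tb$is_deg]
    expect_true(all(cfg$planted_de_genes$gene %in% degs),
                info = paste("seed", seed))
  }
})
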