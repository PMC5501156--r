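two_group_eset <- function(n = 50, na = 5, nb = 5, seed = 1, effect = 0,
                           n_eff = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * (na + nb), 8), n, na + nb,
              dimnames = list(paste0("g", 1:n),
                              paste0("s", 1:(na + nb))))
  if (n_eff > 0) m[1:n_eff, (na + 1):(na + nb)] <-
      m[1:n_eff, (na + 1):(na + nb)] + effect
  pheno <- data.frame(SETS = rep(c("a", "b"), c(na, nb)),
                      SAMPLE_NAME = colnames(m))
  build_eset(m, pheno)
}

test_that("group means and pooled variances equal brute-force loops", {
  eset <- two_group_eset(n = 40, seed = 3)
  fit <- fit_contrasts(eset)
  m <- exprs_of(eset)
  grp <- groups_of(eset)
  for (g in sample(rownames(m), 10)) {
    ma <- mean(m[g, grp == "a"]); mb <- mean(m[g, grp == "b"])
    expect_equal(unname(fit$means[g, "a"]), ma, tolerance = 1e-12)
    expect_equal(unname(fit$means[g, "b"]), mb, tolerance = 1e-12)
    sse <- sum((m[g, grp == "a"] - ma)^2) + sum((m[g, grp == "b"] - mb)^2)
    expect_equal(unname(fit$s2[g]), sse / (ncol(m) - 2), tolerance = 1e-12)
  }
  expect_equal(fit$df, ncol(m) - 2)
  # identical within-group values -> zero variance
  m2 <- matrix(rep(c(1, 2), each = 4), 1, 8,
               dimnames = list("g1", paste0("s", 1:8)))
  e2 <- build_eset(m2, data.frame(SETS = rep(c("a", "b"), each = 4),
                                  SAMPLE_NAME = colnames(m2)))
  f2 <- fit_contrasts(e2)
  expect_equal(unname(f2$s2), 0)
  expect_error(fit_contrasts(two_group_eset(na = 1, nb = 5)),
               class = "exprgraph_validation_error")
})

test_that("variance moderation limits behave as the formulas dictate", {
  set.seed(1)
  s2 <- rchisq(100, 5) / 5
  # d0 = 0: posterior equals the observed variances (ordinary t)
  m0 <- moderate_variances(s2, 10, d0 = 0)
  expect_equal(unname(m0$s2_post), s2)
  # d0 = Inf: posterior collapses to the prior location
  mi <- moderate_variances(s2, 10, d0 = Inf, s0sq = 0.7)
  expect_equal(unname(mi$s2_post), rep(0.7, 100))
  # posterior always lies between s0^2 and s2
  me <- moderate_variances(s2, 10)
  lo <- pmin(s2, me$s0sq); hi <- pmax(s2, me$s0sq)
  expect_true(all(me$s2_post >= lo - 1e-12 & me$s2_post <= hi + 1e-12))
  expect_warning(moderate_variances(s2[1:3], 10), "fewer than 10")
})

test_that("moment matching recovers known prior hyperparameters", {
  set.seed(42)
  d0 <- 4; s0sq <- 0.05; d <- 16; n <- 5000
  sigma2 <- s0sq * d0 / rchisq(n, df = d0)
  s2 <- sigma2 * rchisq(n, df = d) / d
  mod <- moderate_variances(s2, d)
  expect_lt(abs(mod$d0 - d0) / d0, 0.2)
  expect_lt(abs(mod$s0sq - s0sq) / s0sq, 0.2)
})

test_that("moderated statistics match limma's empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  eset <- two_group_eset(n = 200, na = 6, nb = 6, seed = 9, effect = 1.5,
                         n_eff = 15)
  fit <- fit_contrasts(eset)
  mod <- moderate_variances(fit$s2, fit$df)
  de <- test_pairwise(fit, mod)
  design <- cbind(a = as.numeric(groups_of(eset) == "a"),
                  b = as.numeric(groups_of(eset) == "b"))
  lf <- limma::lmFit(exprs_of(eset), design)
  cf <- limma::contrasts.fit(lf, cbind("b-a" = c(-1, 1)))
  eb <- limma::eBayes(cf)
  expect_equal(mod$d0, unname(eb$df.prior), tolerance = 1e-8)
  expect_equal(mod$s0sq, unname(eb$s2.prior), tolerance = 1e-8)
  expect_equal(de$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(de$p_value, unname(eb$p.value[, 1]), tolerance = 1e-10)
})

test_that("two-sided p-values match an independent incomplete-beta oracle", {
  eset <- two_group_eset(n = 100, seed = 5, effect = 2, n_eff = 10)
  fit <- fit_contrasts(eset)
  mod <- moderate_variances(fit$s2, fit$df, d0 = 4, s0sq = 0.8)
  de <- test_pairwise(fit, mod)
  df_tot <- fit$df + 4
  # t-distribution tail via the incomplete beta function, an independent route
  p_oracle <- pbeta(df_tot / (df_tot + de$t^2), df_tot / 2, 0.5)
  expect_equal(de$p_value, p_oracle, tolerance = 1e-10)
})

test_that("selection applies both strict thresholds and direction is signed", {
  fit <- list(means = cbind(a = c(0, 0, 0), b = c(0.5, 2, -2)),
              s2 = c(0.01, 0.01, 0.01), df = 8,
              group_sizes = c(a = 5, b = 5),
              contrasts = data.frame(a = "a", b = "b", label = "b-a"),
              genes = c("g1", "g2", "g3"), symbols = NULL)
  class(fit) <- "de_fit"
  mod <- moderate_variances(fit$s2, fit$df, d0 = 0)
  de <- test_pairwise(fit, mod)
  expect_identical(de$selected, c(FALSE, TRUE, TRUE))
  expect_identical(de$direction, c("up", "up", "down"))
  # fdr below cut but |log2fc| at/below the cut -> not selected
  fit$means <- cbind(a = c(0, 0, 0), b = c(1, 2, -2))
  de2 <- test_pairwise(fit, mod)
  expect_false(de2$selected[1])
  # zero fold-change -> t = 0, p = 1
  fit$means <- cbind(a = c(0, 0, 0), b = c(0, 2, -2))
  de3 <- test_pairwise(fit, mod)
  expect_equal(de3$t[1], 0)
  expect_equal(de3$p_value[1], 1)
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "exprgraph_validation_error")
})

test_that("union across contrasts is plain set union with provenance", {
  de <- data.frame(gene = c("A", "B", "B", "C"),
                   contrast = c("b-a", "b-a", "c-a", "c-a"),
                   selected = c(TRUE, TRUE, TRUE, FALSE))
  u <- union_across_contrasts(de)
  expect_setequal(u$genes, c("A", "B"))
  expect_setequal(u$by_gene$B, c("b-a", "c-a"))
})

test_that("three-group designs test all pairwise contrasts against brute force", {
  set.seed(11)
  m <- matrix(rnorm(30 * 9, 5), 30, 9,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:9)))
  pheno <- data.frame(SETS = rep(c("a", "b", "c"), each = 3),
                      SAMPLE_NAME = colnames(m))
  de <- run_de(build_eset(m, pheno))
  expect_setequal(unique(de$contrast), c("b-a", "c-a", "c-b"))
  g <- "g7"
  mb <- mean(m[g, 4:6]); mc <- mean(m[g, 7:9])
  row <- de[de$gene == g & de$contrast == "c-b", ]
  expect_equal(row$log2fc, mc - mb, tolerance = 1e-12)
})

test_that("the unmoderated path reproduces the ordinary pooled t exactly", {
  eset <- two_group_eset(n = 60, seed = 13, effect = 1, n_eff = 5)
  de <- run_de(eset, moderate = FALSE)
  m <- exprs_of(eset); grp <- groups_of(eset)
  tt <- apply(m, 1, function(x) t.test(x[grp == "b"], x[grp == "a"],
                                       var.equal = TRUE)$statistic)
  expect_equal(de$t, unname(tt), tolerance = 1e-10)
})

test_that("null data stays within the nominal false-positive budget", {
  spec <- simulation_spec(n_genes = 800, n_probes_per_gene = 2,
                          groups = c(control = 6, tumor = 6),
                          n_de_genes = 0, noise_sd = 0.5, seed = 21)
  s <- simulate_experiment(spec)
  norm <- median_polish_summarize(quantile_normalize(s$probe_matrix),
                                  s$probe_map)
  eset <- collapse_to_genes(build_eset(norm, s$phenodata), s$annotation)
  de <- run_de(eset)
  frac <- mean(de$fdr < 0.05)
  mc_err <- sqrt(0.05 * 0.95 / nrow(de))
  expect_lte(frac, 0.05 + 3 * mc_err)
})
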