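test_that("quantile normalization maps columns onto the rank-mean distribution", {
  two <- expr_fixture(cbind(c(1, 2), c(3, 4)))
  out <- as.matrix(quantile_normalize(two)[-1])
  expect_equal(unname(out), cbind(c(2, 3), c(2, 3)))

  same <- expr_fixture(cbind(c(5, 1, 3), c(5, 1, 3)))
  expect_equal(quantile_normalize(same), same)

  set.seed(1)
  rnd <- expr_fixture(matrix(rnorm(200), 40, 5))
  q1 <- quantile_normalize(rnd)
  m <- as.matrix(q1[-1])
  for (j in 2:5) expect_equal(sort(m[, 1]), sort(m[, j]))
  expect_equal(quantile_normalize(q1), q1) # idempotent
})

test_that("the unmoderated t matches the closed-form pooled oracle", {
  e <- expr_fixture(matrix(c(2, 4, 1, 3), nrow = 1), genes = "g01")
  lab <- labels_fixture(2, 2)
  fit <- fit_differential(e, lab, moderated = FALSE)
  expect_equal(fit$table$t, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(fit$table$p_value, 2 * pt(-1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(fit$table$logFC, 1)
  expect_equal(fit$df_residual, 2)

  set.seed(4)
  mat <- matrix(rnorm(50 * 9), 50, 9)
  ef <- expr_fixture(mat)
  lf <- labels_fixture(5, 4)
  fit2 <- fit_differential(ef, lf, moderated = FALSE)
  for (i in c(1, 17, 50)) {
    o <- oracle_pooled_t(mat[i, 1:5], mat[i, 6:9])
    expect_equal(fit2$table$t[i], o$t, tolerance = 1e-12)
    expect_equal(fit2$table$p_value[i], o$p, tolerance = 1e-12)
  }
})

test_that("identical groups give logFC 0 and p 1; p-values stay in (0,1]", {
  half <- matrix(rnorm(40), 20, 2)
  e <- expr_fixture(cbind(half, half))
  lab <- labels_fixture(2, 2)
  for (moderated in c(TRUE, FALSE)) {
    fit <- fit_differential(e, lab, moderated = moderated)
    expect_equal(fit$table$logFC, rep(0, 20))
    expect_equal(fit$table$p_value, rep(1, 20))
    expect_true(all(fit$table$p_value > 0 & fit$table$p_value <= 1))
    expect_true(all(fit$table$adj_p >= fit$table$p_value))
    expect_true(all(fit$table$adj_p <= 1))
  }
  e3 <- expr_fixture(matrix(rnorm(9), 3, 3))
  expect_error(fit_differential(e3, labels_fixture(1, 2)), "2 samples")
})

test_that("the moderated t is the posterior-variance t and hits the pooled t at prior df 0", {
  set.seed(5)
  # heterogeneous true variances keep the estimated prior df finite
  mat <- matrix(rnorm(500 * 13), 500, 13) * exp(rnorm(500, 0, 0.6))
  e <- expr_fixture(mat)
  lab <- labels_fixture(7, 6)
  mod <- fit_differential(e, lab, moderated = TRUE)
  ord <- fit_differential(e, lab, moderated = FALSE)
  expect_gt(mod$df_prior, 0)
  expect_true(is.finite(mod$df_prior))
  expect_equal(mod$table$logFC, ord$table$logFC, tolerance = 1e-12)

  # reconstruct the moderated t from first principles: shrink each pooled
  # variance toward the prior, then rescale the ordinary t
  sp2 <- apply(mat, 1, function(x)
    (6 * var(x[1:7]) + 5 * var(x[8:13])) / 11)
  d0 <- mod$df_prior; s02 <- mod$s2_prior
  s2_post <- (d0 * s02 + 11 * sp2) / (d0 + 11)
  t_manual <- ord$table$t * sqrt(sp2 / s2_post)
  expect_equal(mod$table$t, unname(t_manual), tolerance = 1e-8)
  # the same shrinkage formula with prior df 0 is exactly the pooled t
  expect_equal(ord$table$t * sqrt(sp2 / sp2), ord$table$t)
  # moderated p uses df_residual + df_prior
  expect_equal(mod$table$p_value,
               2 * pt(-abs(mod$table$t), 11 + d0), tolerance = 1e-8)
})

test_that("BH adjustment equals the step-up oracle", {
  set.seed(6)
  for (m in c(1, 17, 400)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-14)
  }
  mat <- matrix(rnorm(200 * 7), 200, 7)
  fit <- fit_differential(expr_fixture(mat), labels_fixture(4, 3))
  expect_equal(fit$table$adj_p, oracle_bh(fit$table$p_value), tolerance = 1e-14)
})

test_that("select_degs partitions by significance and sign", {
  tab <- tibble::tibble(gene_id = c("a", "b", "c"),
                        logFC = c(-1, 2, 3),
                        t = 0, p_value = c(0.01, 1, 1), adj_p = 1)
  out <- suppressMessages(select_degs(tab, alpha = 0.05))
  expect_equal(out$gene_id, "a")
  expect_equal(out$direction, "down")
  none <- suppressMessages(select_degs(dplyr::mutate(tab, p_value = 1)))
  expect_equal(nrow(none), 0)

  # planted recovery at the study conditions: effect 2, noise 0.5, 7v6
  ex <- simulate_expression(sim_config(n_genes = 2000, effect_size = 2,
                                       noise_sd = 0.5, seed = 8))
  fit <- fit_differential(ex$expression, ex$labels)
  degs <- suppressMessages(select_degs(fit))
  planted <- c(ex$truth$de_genes_up, ex$truth$de_genes_down)
  expect_gte(mean(planted %in% degs$gene_id), 0.9)
})

test_that("top-DEG clustering separates the planted conditions", {
  ex <- simulate_expression(sim_config(n_genes = 500, effect_size = 2,
                                       noise_sd = 0.5, seed = 9))
  fit <- fit_differential(ex$expression, ex$labels)
  cl <- suppressWarnings(top_deg_cluster(fit, ex$expression, k = 30))
  expect_lte(length(cl$genes), 60)
  groups <- stats::cutree(cl$sample_tree, 2)
  truth <- ex$labels$condition[match(names(groups), ex$labels$sample_id)]
  expect_equal(rand_index(groups, as.integer(factor(truth))), 1)

  # k = 1 picks the extreme gene in each direction
  d <- tidy(fit)
  cl1 <- suppressWarnings(top_deg_cluster(fit, ex$expression, k = 1))
  up <- d[d$direction == "up", ]
  down <- d[d$direction == "down", ]
  expect_setequal(cl1$genes, c(up$gene_id[which.max(up$logFC)],
                               down$gene_id[which.min(down$logFC)]))

  # duplicated sample columns are at distance 0 and merge first
  m <- matrix(rnorm(40), 10, 4)
  m[, 4] <- m[, 1]
  dup_fit <- fit_differential(expr_fixture(m), labels_fixture(2, 2),
                              moderated = FALSE)
  cld <- suppressWarnings(top_deg_cluster(dup_fit, expr_fixture(m), k = 5,
                                          alpha = 1))
  first <- cld$sample_tree$merge[1, ]
  expect_setequal(-first, c(1, 4))
})
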