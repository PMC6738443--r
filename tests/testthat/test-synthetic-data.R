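test_that("planted DE genes are counted by de_fraction and kept disjoint", {
  cfg <- sim_config(n_genes = 1000, de_fraction = 0.1, effect_size = 2,
                    noise_sd = 0.5, seed = 1)
  ex <- simulate_expression(cfg)
  truth <- ex$truth
  expect_length(c(truth$de_genes_up, truth$de_genes_down), 100)
  expect_length(intersect(truth$de_genes_up, truth$de_genes_down), 0)
  expect_equal(dim(ex$expression), c(1000, 14)) # gene_id + 13 samples
  expect_false(anyNA(ex$expression))
  expect_false(anyDuplicated(ex$expression$gene_id) > 0)

  # null simulation: DE lists exist but group means are equal in expectation
  null_cfg <- sim_config(n_genes = 2000, effect_size = 0, noise_sd = 0.5, seed = 2)
  nx <- simulate_expression(null_cfg)
  expect_gt(length(nx$truth$de_genes_up), 0)
  m <- as.matrix(nx$expression[-1])
  diff <- rowMeans(m[, 1:7]) - rowMeans(m[, 8:13])
  expect_lt(abs(mean(diff)), 0.05) # grand mean difference ~ 0
})

test_that("a fixed seed reproduces the whole study bit-for-bit", {
  cfg <- sim_config(n_genes = 120, n_modules = 2, module_size_range = c(5, 8),
                    module_targets_per_regulator = 4, n_regulators = 6,
                    targets_per_regulator = 15, n_gene_sets = 6,
                    term_size_range = c(15, 60), seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$regulators, s2$regulators)
  expect_identical(s1$gene_sets, s2$gene_sets)
  expect_identical(s1$truth, s2$truth)
})

test_that("degenerate edge probabilities give exactly the planted cliques", {
  cfg <- sim_config(n_genes = 60, n_modules = 3, module_size_range = c(5, 5),
                    p_in = 1, p_out = 0, seed = 3)
  ex <- simulate_expression(cfg)
  net <- simulate_interactions(cfg, ex$expression$gene_id, ex$truth)
  mods <- net$truth$modules
  expect_equal(nrow(net$edges), 3 * choose(5, 2))
  within <- mapply(function(a, b) any(vapply(mods, function(m)
    a %in% m && b %in% m, logical(1))), net$edges$gene_a, net$edges$gene_b)
  expect_true(all(within))
  expect_true(all(net$edges$score >= 0.7 & net$edges$score <= 1))
  expect_true(all(net$edges$gene_a < net$edges$gene_b)) # no loops/duplicates
  expect_lte(nrow(net$edges), 60 * 59 / 2)
})

test_that("p_in = p_out erases the planted density contrast", {
  w_hits <- 0; w_tot <- 0; b_hits <- 0; b_tot <- 0
  for (sd in 1:20) {
    cfg <- sim_config(n_genes = 60, n_modules = 3, module_size_range = c(8, 8),
                      p_in = 0.3, p_out = 0.3, seed = sd)
    ex <- simulate_expression(cfg)
    net <- simulate_interactions(cfg, ex$expression$gene_id, ex$truth)
    mods <- net$truth$modules
    in_mod <- function(a, b) any(vapply(mods, function(m)
      a %in% m && b %in% m, logical(1)))
    within <- mapply(in_mod, net$edges$gene_a, net$edges$gene_b)
    n_w_pairs <- sum(vapply(mods, function(m) choose(length(m), 2), numeric(1)))
    w_hits <- w_hits + sum(within); w_tot <- w_tot + n_w_pairs
    b_hits <- b_hits + sum(!within); b_tot <- b_tot + choose(60, 2) - n_w_pairs
  }
  # both empirical densities must sit within ~4 binomial sd of 0.3
  expect_lt(abs(w_hits / w_tot - 0.3), 4 * sqrt(0.3 * 0.7 / w_tot))
  expect_lt(abs(b_hits / b_tot - 0.3), 4 * sqrt(0.3 * 0.7 / b_tot))
})

test_that("planted regulators overlap their module by construction; nulls by chance", {
  cfg <- sim_config(n_genes = 500, n_modules = 4, module_size_range = c(10, 10),
                    n_regulators = 40, targets_per_regulator = 30,
                    module_targets_per_regulator = 5, seed = 11)
  study <- simulate_study(cfg)
  reg <- study$regulators
  truth <- study$truth
  expect_true(all(reg$class %in% c("ncRNA", "TF")))
  expect_true(all(reg$score >= 0 & reg$score <= 1))
  for (r in names(truth$regulator_targets)) {
    m <- truth$modules[[truth$regulator_targets[[r]]]]
    ov <- length(intersect(reg$target[reg$regulator_id == r], m))
    expect_gte(ov, 5)
  }
  # null regulators: mean overlap with module 1 near targets * m / n_genes
  nulls <- setdiff(unique(reg$regulator_id), names(truth$regulator_targets))
  ovs <- vapply(nulls, function(r)
    length(intersect(reg$target[reg$regulator_id == r], truth$modules[[1]])),
    numeric(1))
  expected <- 30 * 10 / 500
  expect_lt(abs(mean(ovs) - expected), 4 * sqrt(expected / length(ovs)))
})

test_that("gene-set sizes, planted coverage, and GMT round-trip hold", {
  cfg <- sim_config(n_genes = 400, n_modules = 3, module_size_range = c(10, 10),
                    n_gene_sets = 12, seed = 13)
  study <- simulate_study(cfg)
  gs <- study$gene_sets
  sizes <- lengths(gs$genes)
  expect_true(all(sizes >= 15 & sizes <= 200))
  for (term in names(study$truth$enriched_terms)) {
    m <- study$truth$modules[[study$truth$enriched_terms[[term]]]]
    ov <- length(intersect(gs$genes[[which(gs$term_id == term)]], m))
    expect_gte(ov, ceiling(0.6 * length(m)))
  }
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  expect_equal(read_gmt(path), gs)
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_case = 1), "n_case")
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(n_genes = 20, n_modules = 5,
                          module_size_range = c(8, 12)), "module_size_range")
  expect_error(sim_config(n_genes = 100, targets_per_regulator = 150),
               "targets_per_regulator")
  expect_s3_class(tryCatch(sim_config(p_in = 2), error = identity),
                  "modregnet_config_error")
})
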