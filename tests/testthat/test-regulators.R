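test_that("the score filter is boundary-inclusive and collapses duplicates", {
  reg <- tibble::tibble(regulator_id = c("r1", "r1", "r1", "r2", "r2"),
                        class = "ncRNA",
                        target = c("a", "b", "c", "a", "a"),
                        score = c(0.4, 0.5, 0.9, 0.6, 0.8))
  out <- filter_regulators(reg)
  expect_equal(nrow(out), 3) # 0.4 dropped, r2-a deduplicated
  expect_equal(out$score[out$regulator_id == "r2"], 0.8)
  expect_equal(nrow(filter_regulators(reg[0, ])), 0)
  expect_error(filter_regulators(dplyr::select(reg, -score)), "score")
})

test_that("the quantity > 2 AND p < 0.01 rule is reproduced exactly", {
  bg <- sprintf("g%04d", 1:1000)
  module <- bg[1:10]
  mods <- module_set_fixture(list(module))
  # quantity 1: never significant, whatever the p-value
  one <- tibble::tibble(regulator_id = "r", class = "ncRNA",
                        target = module[1], score = 1)
  a1 <- associate_regulators(mods, one, bg)
  expect_equal(a1$quantity, 1L)
  expect_false(a1$significant)
  # quantity 3 but diluted targets in a tiny background: p too large
  small_bg <- bg[1:20]
  mods_small <- module_set_fixture(list(small_bg[1:10]))
  many <- tibble::tibble(regulator_id = "r", class = "ncRNA",
                         target = small_bg[c(1:3, 11:18)], score = 1)
  a2 <- associate_regulators(mods_small, many, small_bg)
  expect_equal(a2$quantity, 3L)
  expect_gt(a2$p_value, 0.01)
  expect_false(a2$significant)
  # planted shape: 5 module targets + 40 decoys against background 1000
  set.seed(13)
  planted <- tibble::tibble(regulator_id = "miR", class = "ncRNA",
                            target = c(module[1:5], sample(bg[11:1000], 40)),
                            score = 1)
  a3 <- associate_regulators(mods, planted, bg)
  expect_true(a3$significant)
  expect_lt(a3$p_value, 1e-4)
  # shared kernel: association p equals the enrichment hypergeometric
  expect_equal(a3$p_value, hypergeom_p(a3$quantity, 45, 10, 1000))
})

test_that("null regulators rarely pass the joint rule", {
  set.seed(14)
  bg <- sprintf("g%04d", 1:1000)
  mods <- module_set_fixture(list(bg[1:10]))
  nulls <- dplyr::bind_rows(lapply(1:500, function(i)
    tibble::tibble(regulator_id = sprintf("n%04d", i), class = "ncRNA",
                   target = sample(bg, 45), score = 1)))
  a <- associate_regulators(mods, nulls, bg)
  expect_lte(mean(a$significant), 0.02)
})

test_that("planted regulators are recovered from the full synthetic study", {
  study <- simulate_study(sim_config(seed = 3))
  mods <- module_set_fixture(study$truth$modules,
                             ids = sprintf("T%02d", seq_along(study$truth$modules)))
  reg <- filter_regulators(study$regulators)
  assoc <- suppressMessages(
    associate_regulators(mods, reg, background = study$expression$gene_id))
  tr <- study$truth$regulator_targets
  hit <- vapply(names(tr), function(r)
    any(assoc$significant & assoc$regulator_id == r &
          assoc$module_id == sprintf("T%02d", tr[[r]])), logical(1))
  expect_gte(mean(hit), 0.9)
  # determinism for fixed inputs
  assoc2 <- suppressMessages(
    associate_regulators(mods, reg, background = study$expression$gene_id))
  expect_identical(assoc, assoc2)
})

test_that("TF-target correlation matches the direct covariance computation", {
  mat <- rbind(tf = c(1, 2, 3, 4), cp = c(2, 4, 6, 8), ng = c(4, 3, 2, 1),
               y = c(1, 2, 3, 5), flat = c(2, 2, 2, 2))
  e <- expr_fixture(mat, genes = rownames(mat))
  out <- tf_target_correlation(e, "tf", c("cp", "ng", "y", "flat", "absent"))
  expect_equal(out$r[out$target == "cp"], 1)
  expect_equal(out$r[out$target == "ng"], -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[out$target == "y"], r_manual, tolerance = 1e-12)
  expect_equal(r_manual, 0.9827, tolerance = 1e-4)
  # p via the t transform on n - 2 df
  tstat <- r_manual * sqrt(2 / (1 - r_manual^2))
  expect_equal(out$p_value[out$target == "y"], 2 * pt(-tstat, 2),
               tolerance = 1e-12)
  expect_false(out$kept[out$target == "flat"])
  expect_equal(out$reason[out$target == "flat"], "zero variance")
  expect_false(out$kept[out$target == "absent"])
  expect_error(tf_target_correlation(e, "missing", "cp"), "missing")
})

test_that("the integrated network expands associations under both filters", {
  mods <- module_set_fixture(list(c("g1", "g2", "g3", "g4")), ids = "M01")
  base_assoc <- tibble::tibble(regulator_id = "miR", regulator_class = "ncRNA",
                               module_id = "M01", quantity = 3L,
                               p_value = 1e-4, significant = TRUE)
  # one significant ncRNA pair, module of 4 genes: 4 regulator->gene edges
  net <- build_integrated_network(base_assoc, mods)
  expect_equal(nrow(net$edges), 4)
  expect_setequal(net$edges$to, c("g1", "g2", "g3", "g4"))
  expect_equal(net$nodes$type[net$nodes$id == "miR"], "ncRNA")

  # no significant associations: empty network
  none <- build_integrated_network(
    dplyr::mutate(base_assoc, significant = FALSE), mods)
  expect_equal(nrow(none$edges), 0)

  # significant TF whose correlations all fail: zero TF edges survive
  tf_assoc <- dplyr::mutate(base_assoc, regulator_id = "tf1",
                            regulator_class = "TF")
  cors <- tibble::tibble(tf_id = "tf1", target = c("g1", "g2", "g3", "g4"),
                         r = 0.1, p_value = 0.9, kept = FALSE, reason = NA)
  tf_net <- build_integrated_network(tf_assoc, mods, correlations = cors)
  expect_equal(nrow(tf_net$edges), 0)

  # gene -> pathway edges come from retained pathway enrichment records
  enr <- tibble::tibble(module_id = "M01", term_id = "PATH1", term_name = "p",
                        category = "pathway", k = 2, K = 10, n = 4, N = 100,
                        p_value = 1e-3, q_value = 1e-2,
                        overlap_genes = list(c("g1", "g2")))
  both <- build_integrated_network(base_assoc, mods, enrichments = enr)
  expect_equal(sum(both$edges$edge_type == "gene-pathway"), 2)
  expect_equal(both$nodes$type[both$nodes$id == "PATH1"], "pathway")
})
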