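# Independent oracles used to freeze expected values. Each is deliberately
# naive (direct enumeration / step-by-step recursion) and shares no code with
# the implementation it checks.

# Benjamini-Hochberg step-up: q_i = min over j >= i (rank order) of p_j * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# hypergeometric upper tail by explicit binomial-coefficient pmf summation
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# GSEA running sum, one explicit step at a time
oracle_es <- function(gene_ids, metrics, gene_set, weight = 1) {
  n <- length(gene_ids)
  hit <- gene_ids %in% gene_set
  nh <- sum(hit)
  denom <- sum(abs(metrics[hit])^weight)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) {
      if (denom == 0) cur + 1 / nh else cur + abs(metrics[i])^weight / denom
    } else cur - 1 / (n - nh)
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# AUC by exhaustive case-control pair comparison, ties counted 1/2
oracle_auc <- function(values, is_case) {
  cases <- values[is_case]
  controls <- values[!is_case]
  total <- 0
  for (x in cases) for (y in controls)
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  total / (length(cases) * length(controls))
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# ordinary pooled two-sample t, closed form
oracle_pooled_t <- function(case, control) {
  n1 <- length(case); n0 <- length(control)
  sp2 <- ((n1 - 1) * var(case) + (n0 - 1) * var(control)) / (n1 + n0 - 2)
  t <- (mean(case) - mean(control)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = t, df = n1 + n0 - 2, p = 2 * pt(-abs(t), n1 + n0 - 2))
}

rand_index <- function(a, b) {
  a <- unname(a); b <- unname(b)
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small expression fixture from an explicit matrix
expr_fixture <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat))),
                         samples = sprintf("s%02d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(genes, samples)
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(mat))
}

labels_fixture <- function(n_case, n_control,
                           samples = sprintf("s%02d", seq_len(n_case + n_control))) {
  tibble::tibble(sample_id = samples,
                 condition = rep(c("case", "control"), c(n_case, n_control)))
}

module_set_fixture <- function(members, ids = sprintf("M%02d", seq_along(members))) {
  structure(tibble::tibble(module_id = ids, size = lengths(members),
                           density = 1, cohesiveness = 1,
                           members = lapply(members, sort)),
            class = c("module_set", class(tibble::tibble())))
}
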