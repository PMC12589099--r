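# Independent oracles used across the suite. Each is a deliberately naive
# implementation of the quantity it checks, kept free of package code.

# BH step-up: p_adj(i) = min over j >= rank(i) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  cummin_rev <- Inf
  for (i in m:1) {
    cummin_rev <- min(cummin_rev, p[ord[i]] * m / i)
    adj[ord[i]] <- min(cummin_rev, 1)
  }
  adj
}

# Right-sided Fisher p by explicit enumeration over the hypergeometric
# support of a 2x2 table with fixed margins.
fisher_right_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 1)
  sum(probs[support >= a])
}

# All-pairs shortest paths by repeated boolean matrix products.
hop_oracle <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(dist) <- 0
  reach <- diag(n) > 0
  step <- adj > 0
  cur <- reach
  for (d in 1:n) {
    cur <- (cur %*% step) > 0
    newly <- cur & !reach & is.infinite(dist)
    dist[newly] <- d
    reach <- reach | cur
  }
  dist
}

# Brute-force extreme-outlier scan under the type-7 quartile convention.
outlier_oracle <- function(v) {
  q <- stats::quantile(v, c(.25, .75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  v < q[1] - 3 * iqr | v > q[2] + 3 * iqr
}

# Textbook Pearson r: covariance over product of population SDs.
pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}

# Transitive ancestor reachability on a parent table, by fixpoint.
closure_oracle <- function(ids, ontology) {
  out <- unique(ids)
  repeat {
    up <- ontology$parent_id[ontology$node_id %in% out]
    up <- up[!is.na(up)]
    new <- setdiff(up, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

# A tiny diamond-shaped ontology below a 2-level broad top: leaf has two
# parents (left, right) that share an ancestor (top).
diamond_ontology <- function() {
  data.frame(
    node_id   = c("root", "broad", "top", "left", "right", "leaf", "leaf"),
    parent_id = c(NA, "root", "broad", "top", "top", "left", "right"),
    level     = c(1, 2, 3, 4, 4, 5, 5))
}

# Small deterministic cohort used by several suites.
small_cohort <- function(seed = 11, missing_rate = 0.03) {
  cohort_config(
    n_individuals = 60, n_proteins = 120, n_metabolites = 12,
    planted = list(planted_enzyme(1, 1, 1.2),
                   planted_transporter(2, 2, -1),
                   planted_adaptor_chain(3, 4, 3, -1, 1),
                   planted_null(5, 4)),
    noise_sd_metabolite = 0.3, missing_rate = missing_rate,
    seed = seed, tissue_labels = "liver")
}
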