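#' Build a combined protein-metabolite interaction graph
#'
#' Assembles an undirected graph whose nodes are proteins and metabolites
#' and whose edges are experimentally supported interactions:
#' protein-metabolite edges (reactions, transporters) and protein-protein
#' edges. Self-loops and metabolite-metabolite edges are rejected;
#' parallel edges from different sources are kept as attributes but
#' collapse to a single adjacency for path queries.
#'
#' @param pm_edges data.frame(protein_id, metabolite_id, source) of
#'   protein-metabolite edges (source in {reaction, transporter}).
#' @param pp_edges data.frame(protein_a, protein_b) of protein-protein
#'   interactions, or NULL.
#' @return An igraph object with vertex attribute `kind`
#'   ({protein, metabolite}) and edge attribute `source`.
#' @export
interaction_graph <- function(pm_edges, pp_edges = NULL) {
  prot <- unique(c(pm_edges$protein_id,
                   if (!is.null(pp_edges)) c(pp_edges$protein_a,
                                             pp_edges$protein_b)))
  met <- unique(pm_edges$metabolite_id)
  if (length(intersect(prot, met)))
    stop("node IDs used as both protein and metabolite: ",
         paste(utils::head(intersect(prot, met)), collapse = ", "))
  el <- rbind(
    data.frame(from = pm_edges$protein_id, to = pm_edges$metabolite_id,
               source = pm_edges$source %||% "reaction"),
    if (!is.null(pp_edges) && nrow(pp_edges))
      data.frame(from = pp_edges$protein_a, to = pp_edges$protein_b,
                 source = "ppi"))
  if (any(el$from == el$to)) stop("self-loop in interaction edges")
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = c(prot, met),
                          kind = c(rep("protein", length(prot)),
                                   rep("metabolite", length(met)))))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(source = function(z)
                     paste(unique(z), collapse = ";")))
}

#' Shortest hop distances between query protein-metabolite pairs
#'
#' Unweighted shortest-path length in the combined interaction graph.
#' Distance 1 is a known physical interaction; 2 or more an indirect
#' functional association. Pairs touching a node absent from the graph,
#' or in a different component, are unreachable (`Inf`).
#'
#' @param graph An [interaction_graph()].
#' @param query_pairs data.frame(protein_id, metabolite_id).
#' @return The query pairs with a numeric `distance` column (Inf =
#'   unreachable).
#' @export
shortest_hop_distances <- function(graph, query_pairs) {
  nodes <- igraph::V(graph)$name
  out <- query_pairs
  out$distance <- Inf
  known <- out$protein_id %in% nodes & out$metabolite_id %in% nodes
  if (any(!known))
    warning(sum(!known), " query pair(s) reference nodes absent from the graph")
  if (any(known)) {
    prot_u <- unique(out$protein_id[known])
    met_u <- unique(out$metabolite_id[known])
    dmat <- igraph::distances(graph, v = prot_u, to = met_u)
    out$distance[known] <- dmat[cbind(match(out$protein_id[known], prot_u),
                                      match(out$metabolite_id[known], met_u))]
  }
  out
}

#' Hop-distance enrichment of top-ranked discovered pairs
#'
#' For each cutoff k and hop distance d, compares the number of top-k
#' pairs at distance d with the count expected if k pairs were drawn at
#' random from the evaluable universe: expected = k * N_d / N, fold =
#' observed / expected. Evaluable pairs are those with a finite distance.
#'
#' @param pair_table data.frame with a `distance` column, rows ordered
#'   best-first (ascending p; ties broken deterministically by the
#'   caller).
#' @param k_grid Integer vector of cutoffs; values beyond the table are
#'   truncated with a warning.
#' @return data.frame(k, distance, observed, expected, fold).
#' @export
topk_hop_enrichment <- function(pair_table, k_grid) {
  dist <- pair_table$distance
  evaluable <- is.finite(dist)
  N <- sum(evaluable)
  if (N == 0) stop("no evaluable pairs (all distances unreachable)")
  strata <- sort(unique(dist[evaluable]))
  Nd <- vapply(strata, function(d) sum(dist == d & evaluable), 1)
  out <- list()
  for (k in k_grid) {
    if (k > nrow(pair_table)) {
      warning("k = ", k, " exceeds ", nrow(pair_table), " ranked pairs; truncated")
      k <- nrow(pair_table)
    }
    top <- dist[seq_len(k)]
    k_eval <- sum(is.finite(top))
    obs <- vapply(strata, function(d) sum(top == d, na.rm = TRUE), 1)
    expected <- k_eval * Nd / N
    out[[length(out) + 1L]] <- data.frame(
      k = k, distance = strata, observed = obs, expected = expected,
      fold = ifelse(expected > 0, obs / expected, NaN))
  }
  do.call(rbind, out)
}

#' Accessory-member Fisher test for one pathway candidate
#'
#' Tests whether a candidate first-degree neighbour of an established
#' pathway is linked to it more often than chance, over the universe of
#' significant covariation edges (protein-protein, protein-metabolite and
#' metabolite-metabolite edges may all be supplied). The 2x2 counts
#' partition the (de-duplicated) edges: a = edges linking the candidate
#' to a pathway member; b = other edges touching the pathway (not the
#' candidate); c = other candidate edges (not touching the pathway);
#' d = edges touching neither. Right-sided exact test.
#'
#' @param pathway_members Character vector of member node IDs.
#' @param candidate Candidate node ID (not a member).
#' @param significant_edges data.frame(node_a, node_b).
#' @param dedupe Collapse parallel edges before counting (default TRUE).
#' @return list(pathway-independent `table` counts, `odds_ratio`, `p`),
#'   or NULL (with a message) when the candidate has no edge to the
#'   pathway.
#' @export
accessory_member_test <- function(pathway_members, candidate,
                                  significant_edges, dedupe = TRUE) {
  stopifnot(!candidate %in% pathway_members)
  ea <- significant_edges$node_a
  eb <- significant_edges$node_b
  if (dedupe) {
    key <- ifelse(ea < eb, paste(ea, eb, sep = "\r"), paste(eb, ea, sep = "\r"))
    keep <- !duplicated(key)
    ea <- ea[keep]; eb <- eb[keep]
  }
  in_pw_a <- ea %in% pathway_members
  in_pw_b <- eb %in% pathway_members
  cand_a <- ea == candidate
  cand_b <- eb == candidate
  touches_pw <- in_pw_a | in_pw_b
  touches_cand <- cand_a | cand_b
  a <- sum(touches_cand & touches_pw)
  if (a == 0) {
    message("candidate ", candidate, " not linked to the pathway; test skipped")
    return(NULL)
  }
  b <- sum(touches_pw & !touches_cand)
  c_ <- sum(touches_cand & !touches_pw)
  d <- sum(!touches_pw & !touches_cand)
  fisher_exact(a, b, c_, d, alternative = "greater")
}

#' Scan all pathways for significant accessory members
#'
#' For every pathway, tests each first-degree neighbour (a node sharing a
#' significant edge with a member without being one) with
#' [accessory_member_test()], then applies BH across all tests.
#'
#' @param pathways Named list of member-ID character vectors.
#' @param significant_edges data.frame(node_a, node_b).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param dedupe Passed through.
#' @return data.frame(pathway_id, candidate_id, a, b, c, d, odds_ratio,
#'   p, p_adj, significant).
#' @export
accessory_member_scan <- function(pathways, significant_edges, alpha = 0.05,
                                  dedupe = TRUE) {
  rows <- list()
  for (pid in names(pathways)) {
    members <- pathways[[pid]]
    touch <- significant_edges$node_a %in% members |
      significant_edges$node_b %in% members
    nb <- setdiff(unique(c(significant_edges$node_a[touch],
                           significant_edges$node_b[touch])), members)
    for (cand in nb) {
      res <- suppressMessages(
        accessory_member_test(members, cand, significant_edges, dedupe))
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pid, candidate_id = cand,
        a = res$table["a"], b = res$table["b"], c = res$table["c"],
        d = res$table["d"], odds_ratio = res$odds_ratio, p = res$p,
        row.names = NULL)
    }
  }
  if (!length(rows))
    return(data.frame(pathway_id = character(), candidate_id = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}

#' Protein-class enrichment among metabolite correlates
#'
#' For each metabolite's set of significantly correlating proteins and
#' each protein class, tests over-representation of the class in the
#' correlate set against the measured background (right-sided exact
#' test), BH-adjusted across all tests.
#'
#' @param correlate_sets Named list: metabolite -> character vector of
#'   significant protein partners.
#' @param class_lists Named list of protein-class ID vectors.
#' @param background Character vector of all measured proteins.
#' @param alpha Adjusted significance level.
#' @return data.frame(set_id, class, n_overlap, n_set, n_class,
#'   n_background, odds_ratio, p, p_adj, significant).
#' @export
class_enrichment <- function(correlate_sets, class_lists, background,
                             alpha = 0.05) {
  background <- unique(background)
  rows <- list()
  for (sid in names(correlate_sets)) {
    set <- intersect(unique(correlate_sets[[sid]]), background)
    if (!length(set)) next
    for (cn in names(class_lists)) {
      cls <- intersect(unique(class_lists[[cn]]), background)
      if (!length(cls)) next
      a <- length(intersect(set, cls))
      b <- length(set) - a
      c_ <- length(cls) - a
      d <- length(background) - a - b - c_
      ft <- fisher_exact(a, b, c_, d, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = sid, class = cn, n_overlap = a, n_set = length(set),
        n_class = length(cls), n_background = length(background),
        odds_ratio = ft$odds_ratio, p = ft$p, row.names = NULL)
    }
  }
  if (!length(rows))
    return(data.frame(set_id = character(), class = character(),
                      n_overlap = integer(), n_set = integer(),
                      n_class = integer(), n_background = integer(),
                      odds_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}

#' Differential abundance and set enrichment between stratifier extremes
#'
#' Splits individuals by the top and bottom `fraction` of a stratifier
#' feature's abundance (ties at the boundary resolved by sample order),
#' computes per-feature linear-scale fold changes (log2 values
#' back-transformed) and Welch two-sided t-tests on the log2 values,
#' calls features up (fold > `fc_up`, p < `p_cut`) or down
#' (fold < `fc_down`, p < `p_cut`), and tests each supplied gene set for
#' enrichment (right-sided exact test, sets below `min_set_size` after
#' background intersection dropped, BH across all tests; only enrichment,
#' not depletion, is considered).
#'
#' @param matrix_ Individuals x features log2 matrix.
#' @param stratifier_feature Column name of the stratifying protein.
#' @param fraction Tail fraction per stratum (default 0.10).
#' @param fc_up,fc_down Linear fold-change thresholds (default 2, 0.5).
#' @param p_cut t-test p threshold (default 0.05).
#' @param gene_sets Named list of feature-ID vectors.
#' @param min_set_size Minimum set size after intersection (default 3).
#' @param alpha Adjusted significance level for the enrichment rows.
#' @return list(up_features, down_features, stats — per-feature fold
#'   change and p, enrichment — per (set, direction) test table).
#' @export
stratified_differential <- function(matrix_, stratifier_feature,
                                    fraction = 0.10, fc_up = 2,
                                    fc_down = 0.5, p_cut = 0.05,
                                    gene_sets = list(), min_set_size = 3,
                                    alpha = 0.05) {
  s <- matrix_[, stratifier_feature]
  ok <- !is.na(s)
  if (length(unique(s[ok])) < 2) stop("stratifier feature is constant")
  n_tail <- floor(fraction * sum(ok))
  if (n_tail < 3) stop("top/bottom fractions must each hold >= 3 individuals")
  ord <- order(s[ok], rownames(matrix_)[ok] %||% seq_len(sum(ok)))
  idx <- which(ok)[ord]
  bottom <- idx[seq_len(n_tail)]
  top <- idx[seq.int(length(idx) - n_tail + 1L, length(idx))]

  feats <- setdiff(colnames(matrix_), stratifier_feature)
  fc <- rep(NA_real_, length(feats)); pv <- rep(NA_real_, length(feats))
  names(fc) <- names(pv) <- feats
  for (f in feats) {
    xt <- matrix_[top, f]; xb <- matrix_[bottom, f]
    xt <- xt[!is.na(xt)]; xb <- xb[!is.na(xb)]
    if (length(xt) < 2 || length(xb) < 2) next
    fc[f] <- mean(2^xt) / mean(2^xb)
    pv[f] <- tryCatch(stats::t.test(xt, xb)$p.value,
                      error = function(e) NA_real_)
  }
  up <- feats[!is.na(fc) & !is.na(pv) & fc > fc_up & pv < p_cut]
  down <- feats[!is.na(fc) & !is.na(pv) & fc < fc_down & pv < p_cut]

  rows <- list()
  for (dir in c("up", "down")) {
    fg <- if (dir == "up") up else down
    if (!length(fg)) next
    for (sn in names(gene_sets)) {
      set <- intersect(unique(gene_sets[[sn]]), feats)
      if (length(set) < min_set_size) next
      a <- length(intersect(fg, set))
      b <- length(fg) - a
      c_ <- length(set) - a
      d <- length(feats) - a - b - c_
      ft <- fisher_exact(a, b, c_, d, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = sn, direction = dir, a = a, n_foreground = length(fg),
        n_set = length(set), odds_ratio = ft$odds_ratio, p = ft$p,
        row.names = NULL)
    }
  }
  enrichment <- if (length(rows)) {
    e <- do.call(rbind, rows)
    e$p_adj <- bh_adjust(e$p)
    e$significant <- e$p_adj < alpha
    e
  } else {
    data.frame(set_id = character(), direction = character(), a = integer(),
               n_foreground = integer(), n_set = integer(),
               odds_ratio = numeric(), p = numeric(), p_adj = numeric(),
               significant = logical())
  }
  list(up_features = up, down_features = down,
       stats = data.frame(feature_id = feats, fold_change = unname(fc),
                          p = unname(pv)),
       enrichment = enrichment)
}
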