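test_that("ancestor closure handles leaves, chains and diamonds", {
  ont <- diamond_ontology()
  # no parents below the cutoff: closure is the direct IDs alone
  expect_setequal(ancestor_closure("leaf", ont, excluded_top_levels = 4),
                  "leaf")
  # chain with the cutoff at the default: everything above level 3 excluded
  expect_setequal(ancestor_closure("leaf", ont, excluded_top_levels = 3),
                  c("leaf", "left", "right"))
  # full diamond vs brute-force reachability oracle (minus the cutoff)
  lev <- setNames(ont$level[!duplicated(ont$node_id)],
                  ont$node_id[!duplicated(ont$node_id)])
  oracle <- closure_oracle("leaf", ont)
  expect_setequal(ancestor_closure("leaf", ont, excluded_top_levels = 0),
                  oracle)
  expect_error(ancestor_closure("nope", ont), "nope")
})

test_that("succinate-style chains map through charge-state and class nodes", {
  ont <- data.frame(
    node_id = c(paste0("L", 1:6), "diacid_dianion", "succinate2-",
                "succinate"),
    parent_id = c(NA, paste0("L", 1:5), "L6", "diacid_dianion",
                  "succinate2-"),
    level = c(1:6, 7, 8, 9))
  cl <- ancestor_closure("succinate", ont)
  expect_setequal(cl, c("succinate", "succinate2-", "diacid_dianion"))
})

test_that("closure equals the reachability oracle on random DAGs", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(5:50, 1)
    ids <- paste0("n", 1:n)
    rows <- list()
    for (i in 2:n) {
      np <- sample(1:min(3, i - 1), 1)
      for (pa in sample(ids[1:(i - 1)], np))
        rows[[length(rows) + 1]] <- data.frame(node_id = ids[i],
                                               parent_id = pa)
    }
    ont <- rbind(data.frame(node_id = "n1", parent_id = NA),
                 do.call(rbind, rows))
    start <- sample(ids, 1)
    expect_setequal(ancestor_closure(start, ont, excluded_top_levels = 0),
                    closure_oracle(start, ont))
  }
})

test_that("level fallback assigns longest-path depths", {
  ont <- diamond_ontology()[, c("node_id", "parent_id")]
  lev <- ontology_levels(ont)
  expect_equal(unname(lev[c("root", "broad", "top", "left", "leaf")]),
               c(1, 2, 3, 4, 5))
})

test_that("reference-edge construction respects cardinality and dedup", {
  rx <- data.frame(record_id = c("R1", "R1", "R1", "R2"),
                   protein_id = "E1",
                   metabolite_node = c("s1", "s2", "pr1", "s1"),
                   role = c("substrate", "substrate", "product", "substrate"))
  edges <- build_reference_edges(reaction_table = rx)
  expect_equal(nrow(edges), 3)           # (E1,s1) deduped across R1, R2
  e <- edges[edges$metabolite_node == "s1", ]
  expect_equal(e$source_record_ids, "R1;R2")

  tx <- data.frame(protein_id = "T1", metabolite_node = c("m1", "m2", "m3"))
  expect_equal(nrow(build_reference_edges(transporter_table = tx)), 3)

  pw <- data.frame(pathway_id = "PW1",
                   member_id = c("E1", "E2", "m1"),
                   member_kind = c("protein", "protein", "metabolite"))
  pwe <- build_reference_edges(pathway_table = pw)
  expect_equal(nrow(pwe), 2)
  expect_setequal(pwe$protein_id, c("E1", "E2"))

  bad <- data.frame(record_id = "R9", protein_id = NA,
                    metabolite_node = "x", role = "substrate")
  expect_warning(out <- build_reference_edges(reaction_table = bad),
                 "skipping")
  expect_equal(nrow(out), 0)
})

test_that("restriction to measured space follows the closure", {
  ont <- data.frame(
    node_id = c(paste0("L", 1:6), "classA", "leafA"),
    parent_id = c(NA, paste0("L", 1:5), "L6", "classA"),
    level = c(1:6, 7, 8))
  idents <- data.frame(measured_id = "metA", node_id = "leafA")
  edges <- build_reference_edges(reaction_table = data.frame(
    record_id = c("R1", "R2", "R3"),
    protein_id = c("E1", "E1", "E2"),
    metabolite_node = c("leafA", "classA", "L6"),
    role = "substrate"))
  mp <- restrict_to_measured(edges, c("E1", "E2"), idents, ont)
  # direct edge and class-level (closure) edge kept; above-cutoff edge not
  expect_setequal(mp$edges$metabolite_node, c("leafA", "classA"))
  expect_true(all(mp$mapping$measured_id == "metA"))
  # unmeasured protein's edges dropped
  mp2 <- restrict_to_measured(edges, "E2", idents, ont)
  expect_equal(nrow(mp2$edges), 0)
})

test_that("restriction is monotone in the measured metabolite set", {
  ont <- data.frame(
    node_id = c(paste0("L", 1:6), "c1", "m1", "m2"),
    parent_id = c(NA, paste0("L", 1:5), "L6", "c1", "c1"),
    level = c(1:6, 7, 8, 8))
  edges <- build_reference_edges(reaction_table = data.frame(
    record_id = c("R1", "R2"), protein_id = "E",
    metabolite_node = c("m1", "c1"), role = "s"))
  small <- restrict_to_measured(edges, "E",
                                data.frame(measured_id = "A", node_id = "m1"),
                                ont)
  big <- restrict_to_measured(edges, "E",
                              data.frame(measured_id = c("A", "B"),
                                         node_id = c("m1", "m2")), ont)
  keys <- function(mp) paste(mp$edges$protein_id, mp$edges$metabolite_node)
  expect_true(all(keys(small) %in% keys(big)))
})

test_that("recapitulation rate counts matched mappable edges", {
  ont <- data.frame(node_id = c(paste0("L", 1:6), "n1", "n2", "n3", "n4"),
                    parent_id = c(NA, paste0("L", 1:5), "L6", "L6", "L6",
                                  "L6"),
                    level = c(1:6, 7, 7, 7, 7))
  idents <- data.frame(measured_id = paste0("M", 1:4),
                       node_id = paste0("n", 1:4))
  edges <- build_reference_edges(reaction_table = data.frame(
    record_id = paste0("R", 1:4), protein_id = paste0("E", 1:4),
    metabolite_node = paste0("n", 1:4), role = "s"))
  mp <- restrict_to_measured(edges, paste0("E", 1:4), idents, ont)
  recs <- data.frame(tissue = "t", protein_id = "E1", metabolite_id = "M1",
                     n_obs = 50L, r = .8, p = 1e-9, p_adj = 1e-8,
                     significant = TRUE, sign_class = "co-operative")
  rr <- recapitulation_rate(recs, mp)
  expect_equal(rr$n_mappable, 4)
  expect_equal(rr$n_recapitulated, 1)
  expect_equal(rr$fraction, 0.25)
  # antagonistic records excluded by default, included on request
  recs$sign_class <- "antagonistic"
  expect_equal(recapitulation_rate(recs, mp)$n_recapitulated, 0)
  expect_equal(recapitulation_rate(recs, mp,
                                   include_antagonistic = TRUE)$n_recapitulated,
               1)
  # all matched
  recs4 <- data.frame(tissue = "t", protein_id = paste0("E", 1:4),
                      metabolite_id = paste0("M", 1:4), n_obs = 50L, r = .8,
                      p = 1e-9, p_adj = 1e-8, significant = TRUE,
                      sign_class = "co-operative")
  expect_equal(recapitulation_rate(recs4, mp)$fraction, 1)
  empty <- mp; empty$edges <- empty$edges[0, ]
  expect_warning(rr0 <- recapitulation_rate(recs4, empty), "undefined")
  expect_true(is.nan(rr0$fraction))
})

test_that("exact Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact(5, 0, 0, 5)$p, 1 / choose(10, 5),
               tolerance = 1e-12)
  ft <- fisher_exact(1, 9, 9, 81)
  expect_equal(ft$odds_ratio, 1)
  expect_equal(ft$p, fisher_right_oracle(1, 9, 9, 81), tolerance = 1e-12)

  set.seed(3)
  for (i in 1:60) {
    N <- sample(4:60, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    expect_equal(fisher_exact(a, b, c_, d)$p,
                 fisher_right_oracle(a, b, c_, d), tolerance = 1e-10)
    # cross-check against the standard exact test
    expect_equal(fisher_exact(a, b, c_, d)$p,
                 fisher.test(matrix(c(a, c_, b, d), 2),
                             alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  expect_warning(d0 <- fisher_exact(0, 0, 3, 4), "degenerate")
  expect_equal(d0$p, 1)
})

test_that("recapitulation Fisher test assembles the 2x2 from pair sets", {
  uni <- paste0("u", 1:10)
  res <- fisher_recapitulation(uni[1:5], uni[1:5], uni)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_error(fisher_recapitulation("zzz", uni[1], uni), "subsets")
})
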