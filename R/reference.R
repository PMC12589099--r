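#' Ontology ancestor closure of a metabolite identity
#'
#' A measured metabolite is identified by one or more direct ontology IDs
#' (itself, conjugate acids/bases, salt adducts, charge states, synonyms).
#' Its ancestor closure is the set of those IDs plus every ancestor
#' reachable through the parent graph, minus nodes in the broad top levels
#' of the hierarchy (excluded to prevent false positives from ambiguous
#' class-level matches). The closure lets a class-level reference edge
#' (e.g. enzyme - "a long-chain fatty acid") be recapitulated by a
#' measured member of the class (e.g. myristic acid).
#'
#' @param direct_ids Character vector of direct ontology node IDs.
#' @param ontology data.frame(node_id, parent_id, level); multiple rows
#'   per node for multiple parents; `parent_id` NA for roots. Missing
#'   levels are filled by longest-path depth from the roots (root =
#'   level 1).
#' @param excluded_top_levels Nodes with level <= this are dropped from
#'   the closure (default 6).
#' @return Character vector of node IDs.
#' @export
ancestor_closure <- function(direct_ids, ontology, excluded_top_levels = 6) {
  nodes <- unique(ontology$node_id)
  unknown <- setdiff(direct_ids, nodes)
  if (length(unknown))
    stop("unknown ontology ID(s): ", paste(unknown, collapse = ", "))
  parents <- split(ontology$parent_id, ontology$node_id)
  closure <- character()
  frontier <- unique(direct_ids)
  while (length(frontier)) {
    closure <- c(closure, frontier)
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(up[!is.na(up)], closure)
  }
  lev <- ontology_levels(ontology)
  closure[lev[closure] > excluded_top_levels]
}

#' Node levels of an ontology, with a longest-path fallback
#'
#' Uses declared levels where present; otherwise assigns roots level 1 and
#' every other node 1 + the maximum level among its parents (longest path
#' from a root), so a child always sits strictly below each parent.
#'
#' @param ontology data.frame(node_id, parent_id, level (optional)).
#' @return Named integer vector of levels.
#' @export
ontology_levels <- function(ontology) {
  ids <- unique(ontology$node_id)
  declared <- rep(NA_integer_, length(ids))
  names(declared) <- ids
  if ("level" %in% names(ontology)) {
    first <- !duplicated(ontology$node_id)
    declared[ontology$node_id[first]] <- as.integer(ontology$level[first])
  }
  if (!anyNA(declared)) return(declared)
  parents <- split(ontology$parent_id, ontology$node_id)
  lev <- declared
  depth_of <- function(id, seen = character()) {
    if (!is.na(lev[id])) return(lev[id])
    if (id %in% seen) stop("cycle in ontology at node ", id)
    ps <- parents[[id]]
    ps <- ps[!is.na(ps)]
    d <- if (!length(ps)) 1L else
      1L + max(vapply(ps, depth_of, 1L, seen = c(seen, id)))
    lev[id] <<- d
    d
  }
  for (id in ids) depth_of(id)
  lev
}

#' Build reference protein-metabolite edges from knowledge tables
#'
#' Converts reaction, transporter and pathway records into one undirected
#' edge per (protein, metabolite ontology node) per source kind,
#' de-duplicated within kind; an edge appearing in several records keeps
#' all source record IDs. Reaction tables contribute one edge per enzyme x
#' substrate/product; transporter tables one edge per transporter x
#' transported metabolite; pathway tables one edge per protein member x
#' metabolite member within a pathway record (the input table is expected
#' to list direct interactions and upstream/downstream regulation as
#' memberships).
#'
#' @param reaction_table data.frame(record_id, protein_id,
#'   metabolite_node, role) or NULL.
#' @param transporter_table data.frame(protein_id, metabolite_node) or
#'   NULL.
#' @param pathway_table data.frame(pathway_id, member_id, member_kind)
#'   or NULL.
#' @return data.frame(protein_id, metabolite_node, source,
#'   source_record_ids) with source in {reaction, transporter, pathway}.
#' @export
build_reference_edges <- function(reaction_table = NULL,
                                  transporter_table = NULL,
                                  pathway_table = NULL) {
  out <- list()
  add <- function(protein, node, source, record) {
    ok <- !is.na(protein) & protein != "" & !is.na(node) & node != ""
    if (any(!ok)) warning("skipping ", sum(!ok),
                          " record(s) lacking a protein or metabolite")
    if (!any(ok)) return()
    out[[length(out) + 1L]] <<- data.frame(
      protein_id = protein[ok], metabolite_node = node[ok],
      source = source, source_record_id = record[ok])
  }
  if (!is.null(reaction_table) && nrow(reaction_table))
    add(reaction_table$protein_id, reaction_table$metabolite_node,
        "reaction", reaction_table$record_id)
  if (!is.null(transporter_table) && nrow(transporter_table))
    add(transporter_table$protein_id, transporter_table$metabolite_node,
        "transporter",
        transporter_table$record_id %||%
          paste0("T", seq_len(nrow(transporter_table))))
  if (!is.null(pathway_table) && nrow(pathway_table)) {
    for (pw in unique(pathway_table$pathway_id)) {
      sub <- pathway_table[pathway_table$pathway_id == pw, , drop = FALSE]
      prot <- sub$member_id[sub$member_kind == "protein"]
      met <- sub$member_id[sub$member_kind == "metabolite"]
      if (length(prot) && length(met)) {
        grid <- expand.grid(protein_id = prot, metabolite_node = met,
                            stringsAsFactors = FALSE)
        add(grid$protein_id, grid$metabolite_node, "pathway", pw)
      }
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), metabolite_node = character(),
                      source = character(), source_record_ids = character()))
  long <- do.call(rbind, out)
  key <- paste(long$source, long$protein_id, long$metabolite_node, sep = "\r")
  recs <- vapply(split(long$source_record_id, key),
                 function(z) paste(unique(z), collapse = ";"), "")
  first <- long[!duplicated(key), c("protein_id", "metabolite_node", "source")]
  first$source_record_ids <- recs[paste(first$source, first$protein_id,
                                        first$metabolite_node, sep = "\r")]
  rownames(first) <- NULL
  first
}

#' Restrict reference edges to the measured feature space
#'
#' A reference edge is mappable iff its protein was measured and its
#' metabolite node lies in the ancestor closure of at least one measured
#' metabolite. The returned mapping records which measured metabolite(s)
#' reach each retained edge, so a class-level edge is credited to its
#' measured member(s).
#'
#' @param edges Output of [build_reference_edges()].
#' @param measured_proteins Character vector of measured protein IDs.
#' @param identities data.frame(measured_id, node_id): direct ontology
#'   IDs per measured metabolite (several rows allowed).
#' @param ontology Ontology table (see [ancestor_closure()]).
#' @param excluded_top_levels Passed to [ancestor_closure()].
#' @return list(edges = mappable subset of `edges`, mapping =
#'   data.frame(measured_id, protein_id, metabolite_node, source)).
#' @export
restrict_to_measured <- function(edges, measured_proteins, identities,
                                 ontology, excluded_top_levels = 6) {
  meas <- unique(identities$measured_id)
  closures <- lapply(meas, function(mid) {
    ancestor_closure(identities$node_id[identities$measured_id == mid],
                     ontology, excluded_top_levels)
  })
  names(closures) <- meas
  node2meas <- utils::stack(stats::setNames(closures, meas))
  # stack gives values (node) / ind (measured)
  node2meas <- data.frame(node = as.character(node2meas$values),
                          measured_id = as.character(node2meas$ind))
  keep <- edges$protein_id %in% measured_proteins &
    edges$metabolite_node %in% node2meas$node
  mappable <- edges[keep, , drop = FALSE]
  rownames(mappable) <- NULL
  mapping <- merge(mappable[, c("protein_id", "metabolite_node", "source")],
                   node2meas, by.x = "metabolite_node", by.y = "node")
  mapping <- mapping[, c("measured_id", "protein_id", "metabolite_node",
                         "source")]
  mapping <- mapping[order(mapping$measured_id, mapping$protein_id), ]
  rownames(mapping) <- NULL
  list(edges = mappable, mapping = mapping)
}

#' Fraction of mappable reference edges recapitulated by covariation
#'
#' A mappable edge is recapitulated iff at least one significant
#' covariation record links its protein to a measured metabolite that
#' maps onto the edge's ontology node. By default only co-operative
#' (significant, positive-r) records count, since recapitulation of
#' enzyme-substrate relationships is reported on co-operative pairs;
#' `include_antagonistic = TRUE` widens to all significant records.
#'
#' @param records Correlation records after [adjust_bh()].
#' @param mappable Result of [restrict_to_measured()].
#' @param include_antagonistic Also count significant negative pairs.
#' @return list(n_recapitulated, n_mappable, fraction, edges — the
#'   mappable edges with a logical `recapitulated` flag).
#' @export
recapitulation_rate <- function(records, mappable,
                                include_antagonistic = FALSE) {
  edges <- mappable$edges
  if (!nrow(edges)) {
    warning("no mappable edges; recapitulation fraction undefined")
    return(list(n_recapitulated = 0L, n_mappable = 0L, fraction = NaN,
                edges = edges))
  }
  sig <- records[which(records$significant), , drop = FALSE]
  if (!include_antagonistic)
    sig <- sig[sig$sign_class == "co-operative", , drop = FALSE]
  sig_keys <- unique(paste(sig$protein_id, sig$metabolite_id, sep = "\r"))
  map_keys <- paste(mappable$mapping$protein_id, mappable$mapping$measured_id,
                    sep = "\r")
  hit_map <- mappable$mapping[map_keys %in% sig_keys, , drop = FALSE]
  hit_edge_keys <- unique(paste(hit_map$source, hit_map$protein_id,
                                hit_map$metabolite_node, sep = "\r"))
  edge_keys <- paste(edges$source, edges$protein_id, edges$metabolite_node,
                     sep = "\r")
  edges$recapitulated <- edge_keys %in% hit_edge_keys
  list(n_recapitulated = sum(edges$recapitulated),
       n_mappable = nrow(edges),
       fraction = mean(edges$recapitulated),
       edges = edges)
}

#' Fisher's exact test for recapitulation enrichment
#'
#' Tests whether significant covariation pairs are enriched for known
#' reference pairs over the universe of evaluable pairs (2x2:
#' significant x known). Right-sided by default.
#'
#' @param significant_pairs,known_pairs,universe_pairs Character vectors
#'   of pair keys (e.g. `paste(protein, metabolite)`); both argument sets
#'   must be subsets of the universe.
#' @param alternative Passed to [fisher_exact()].
#' @return list(odds_ratio, p, table).
#' @export
fisher_recapitulation <- function(significant_pairs, known_pairs,
                                  universe_pairs,
                                  alternative = c("greater", "two.sided")) {
  universe_pairs <- unique(universe_pairs)
  significant_pairs <- unique(significant_pairs)
  known_pairs <- unique(known_pairs)
  if (length(setdiff(significant_pairs, universe_pairs)) ||
      length(setdiff(known_pairs, universe_pairs)))
    stop("significant and known pairs must be subsets of the universe")
  a <- length(intersect(significant_pairs, known_pairs))
  b <- length(significant_pairs) - a
  c_ <- length(known_pairs) - a
  d <- length(universe_pairs) - a - b - c_
  fisher_exact(a, b, c_, d, alternative = match.arg(alternative))
}
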