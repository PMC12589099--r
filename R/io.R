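#' Read an abundance matrix from TSV
#'
#' Format: tab-separated, UTF-8, first column `sample_id`, header row of
#' feature IDs, empty cell = missing, lines starting with `#` ignored.
#' Duplicate sample or feature IDs, ragged rows and non-numeric cells are
#' errors citing the offending location.
#'
#' @param path File path.
#' @return Numeric matrix, rownames = sample IDs, colnames = feature IDs.
#' @export
read_abundance_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop(path, ": empty file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  feats <- header[-1]
  if (anyDuplicated(feats))
    stop(path, ": duplicate feature ID '", feats[duplicated(feats)][1], "'")
  body <- cells[-1]
  width <- lengths(body)
  # trailing empty cells are dropped by strsplit; pad, but flag over-long rows
  if (any(width > length(header)))
    stop(path, ": ragged row at line ", which(width > length(header))[1] + 1)
  samples <- vapply(body, `[`, "", 1)
  if (anyDuplicated(samples))
    stop(path, ": duplicate sample ID '", samples[duplicated(samples)][1], "'")
  mat <- matrix(NA_real_, length(body), length(feats),
                dimnames = list(samples, feats))
  for (i in seq_along(body)) {
    row <- body[[i]][-1]
    row <- c(row, rep("", length(feats) - length(row)))
    nonempty <- row != ""
    v <- suppressWarnings(as.numeric(row[nonempty]))
    if (anyNA(v)) {
      bad <- which(nonempty)[which(is.na(v))[1]]
      stop(path, ": non-numeric cell at line ", i + 1, ", column ",
           feats[bad], ": '", row[bad], "'")
    }
    mat[i, nonempty] <- v
  }
  mat
}

#' Write an abundance matrix to TSV
#'
#' Inverse of [read_abundance_matrix()]; finite values are written with
#' full precision (`%.17g`) so write-then-read is bit-exact, and missing
#' entries as empty cells.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(mat, path) {
  txt <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  txt[is.na(mat)] <- ""
  lines <- c(paste(c("sample_id", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(z) sprintf("%.17g", z))
  df[num] <- lapply(df[num], function(z) ifelse(z == "NA", "", z))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Write a simulated cohort and its knowledge tables to a directory
#'
#' Emits per-tissue protein/metabolite matrices, the reference-knowledge
#' TSVs, the truth edges and the generating configuration (JSON).
#'
#' @param dataset A `cohort_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in names(dataset$proteins)) {
    write_abundance_matrix(dataset$proteins[[t]],
                           file.path(dir, paste0("proteins_", t, ".tsv")))
    write_abundance_matrix(dataset$metabolites[[t]],
                           file.path(dir, paste0("metabolites_", t, ".tsv")))
  }
  write_tsv_table(dataset$truth_edges, file.path(dir, "truth_edges.tsv"))
  kn <- dataset$knowledge
  write_tsv_table(kn$reaction_edges, file.path(dir, "reaction_edges.tsv"))
  write_tsv_table(kn$transporter_edges, file.path(dir, "transporter_edges.tsv"))
  write_tsv_table(kn$pathway_memberships,
                  file.path(dir, "pathway_memberships.tsv"))
  write_tsv_table(kn$ppi_edges, file.path(dir, "ppi_edges.tsv"))
  write_tsv_table(kn$ontology, file.path(dir, "ontology.tsv"))
  write_tsv_table(kn$identity, file.path(dir, "identity.tsv"))
  cls <- utils::stack(lapply(kn$class_lists, as.character))
  write_tsv_table(data.frame(class = as.character(cls$ind),
                             protein_id = as.character(cls$values)),
                  file.path(dir, "class_lists.tsv"))
  cfg <- dataset$config
  cfg$planted <- lapply(cfg$planted, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read reference-knowledge tables from a directory
#' @param dir Directory written by [write_cohort()].
#' @return A `reference_knowledge` list.
#' @export
read_knowledge <- function(dir) {
  cls <- read_tsv_table(file.path(dir, "class_lists.tsv"))
  structure(list(
    reaction_edges = read_tsv_table(file.path(dir, "reaction_edges.tsv")),
    transporter_edges = read_tsv_table(file.path(dir, "transporter_edges.tsv")),
    pathway_memberships = read_tsv_table(file.path(dir,
                                                   "pathway_memberships.tsv")),
    ppi_edges = read_tsv_table(file.path(dir, "ppi_edges.tsv")),
    ontology = read_tsv_table(file.path(dir, "ontology.tsv")),
    identity = read_tsv_table(file.path(dir, "identity.tsv")),
    class_lists = split(cls$protein_id, cls$class)),
    class = "reference_knowledge")
}

#' Run the full covariation-architecture pipeline
#'
#' Orchestrates: cohort simulation (or reading matrices from disk) ->
#' pairwise correlation with BH control and sign classification ->
#' reference-edge mapping and recapitulation -> LASSO predictor
#' nomination with post-selection FDR, extreme-outlier flags, validation
#' scores and annotation -> hop-distance network enrichment -> evaluation
#' against truth edges where available. Each stage's tables are written
#' under `out_dir` before the next begins; the returned manifest records
#' file checksums and row counts, and reruns of an identical
#' configuration reproduce identical checksums.
#'
#' @param run_config list with elements: either `simulate` (arguments for
#'   [cohort_config()]) or `input_dir` (a directory written by
#'   [write_cohort()]); `out_dir`; optional `alpha` (0.05), `min_obs`
#'   (20), `lasso` (arguments for [lasso_config()]), `k_grid`
#'   (c(10, 50, 100)), `decoy_edges` (0), `contaminant_signature`
#'   (protein IDs for the QC stage; omitted = no QC removal).
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(run_config) {
  rc <- run_config
  stopifnot(!is.null(rc$out_dir))
  alpha <- rc$alpha %||% 0.05
  min_obs <- rc$min_obs %||% 20
  k_grid <- rc$k_grid %||% c(10, 50, 100)
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), warnings = character())
  stage_files <- function(stage, files) {
    manifest$stages[[stage]] <<- lapply(stats::setNames(files, basename(files)),
      function(f) list(md5 = unname(tools::md5sum(f)),
                       rows = length(readLines(f)) - 1L))
  }

  stage <- "input"
  res <- tryCatch({
    if (!is.null(rc$simulate)) {
      cfg <- do.call(cohort_config, rc$simulate)
      sim <- simulate_cohort(cfg)
      if ((rc$decoy_edges %||% 0) > 0)
        sim$knowledge <- simulate_reference_knowledge(
          cfg, decoy_edges = rc$decoy_edges)
      ddir <- file.path(rc$out_dir, "cohort")
      write_cohort(sim, ddir)
      sim
    } else {
      if (is.null(rc$input_dir) || !dir.exists(rc$input_dir))
        stop("input_dir missing or nonexistent")
      tissues <- sub("^proteins_(.*)\\.tsv$", "\\1",
                     list.files(rc$input_dir, pattern = "^proteins_.*\\.tsv$"))
      if (!length(tissues)) stop("no protein matrices found in input_dir")
      proteins <- metabolites <- list()
      for (t in tissues) {
        proteins[[t]] <- read_abundance_matrix(
          file.path(rc$input_dir, paste0("proteins_", t, ".tsv")))
        mpath <- file.path(rc$input_dir, paste0("metabolites_", t, ".tsv"))
        if (!file.exists(mpath)) stop("metabolite matrix missing for ", t)
        metabolites[[t]] <- read_abundance_matrix(mpath)
      }
      tpath <- file.path(rc$input_dir, "truth_edges.tsv")
      list(proteins = proteins, metabolites = metabolites,
           knowledge = read_knowledge(rc$input_dir),
           truth_edges = if (file.exists(tpath)) read_tsv_table(tpath))
    }
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  sim <- res

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  run_stage("qc", {
    if (!is.null(rc$contaminant_signature)) {
      for (t in names(sim$proteins)) {
        qc <- flag_contaminant_proteins(sim$proteins[[t]],
                                        rc$contaminant_signature)
        if (length(qc$removed_feature_ids)) {
          keep <- setdiff(colnames(sim$proteins[[t]]),
                          qc$removed_feature_ids)
          sim$proteins[[t]] <- sim$proteins[[t]][, keep, drop = FALSE]
          write_tsv_table(
            data.frame(feature_id = qc$removed_feature_ids,
                       reason = unname(qc$removal_reason)),
            file.path(rc$out_dir, paste0("qc_removed_", t, ".tsv")))
        }
      }
    }
    NULL
  })

  records <- run_stage("correlate", {
    recs <- do.call(rbind, lapply(names(sim$proteins), function(t)
      correlate_all(sim$proteins[[t]], sim$metabolites[[t]],
                    min_obs = min_obs, tissue = t)))
    recs <- adjust_bh(recs, alpha = alpha)
    f <- file.path(rc$out_dir, "correlations.tsv")
    write_tsv_table(recs, f)
    # graph-viewer export: unique significant pairs across tissues,
    # keeping each pair once with its strongest record
    sig <- recs[which(recs$significant), , drop = FALSE]
    sig <- sig[order(sig$p_adj, -abs(sig$r)), ]
    sig <- sig[!duplicated(paste(sig$protein_id, sig$metabolite_id)), ]
    f2 <- file.path(rc$out_dir, "significant_edges.tsv")
    write_tsv_table(data.frame(node_a = sig$protein_id,
                               node_b = sig$metabolite_id,
                               sign_class = sig$sign_class,
                               r = sig$r, p_adj = sig$p_adj), f2)
    stage_files("correlate", c(f, f2))
    recs
  })

  mapped <- run_stage("map", {
    kn <- sim$knowledge
    edges <- build_reference_edges(kn$reaction_edges, kn$transporter_edges,
                                   kn$pathway_memberships)
    measured_prot <- unique(unlist(lapply(sim$proteins, colnames)))
    mp <- restrict_to_measured(edges, measured_prot, kn$identity, kn$ontology)
    recap <- lapply(stats::setNames(nm = unique(records$tissue)), function(t)
      recapitulation_rate(records[records$tissue == t, ], mp))
    f1 <- file.path(rc$out_dir, "mappable_edges.tsv")
    write_tsv_table(mp$edges, f1)
    jsonlite::write_json(
      lapply(recap, function(z) z[c("n_recapitulated", "n_mappable",
                                    "fraction")]),
      file.path(rc$out_dir, "recapitulation.json"), auto_unbox = TRUE,
      digits = NA)
    stage_files("map", f1)
    mp
  })

  assoc <- run_stage("lasso", {
    lcfg <- do.call(lasso_config, rc$lasso %||% list())
    fits <- list()
    for (t in names(sim$proteins))
      fits <- c(fits, nominate_predictors(sim$proteins[[t]],
                                          sim$metabolites[[t]], lcfg,
                                          tissue = t))
    if (!length(fits) || !any(vapply(fits, function(f)
      length(f$selected) > 0, TRUE))) {
      manifest$warnings <<- c(manifest$warnings, "no nonzero LASSO selections")
      NULL
    } else {
      a <- post_selection_fdr(fits, sim$proteins, sim$metabolites, lcfg,
                              alpha = alpha)
      a <- flag_extreme_outliers(a)
      a <- annotate_associations(a, sim$knowledge)
      scores <- compute_validation_scores(a, mapped$mapping)
      f1 <- file.path(rc$out_dir, "associations.tsv")
      f2 <- file.path(rc$out_dir, "validation_scores.tsv")
      write_tsv_table(a, f1)
      write_tsv_table(scores, f2)
      stage_files("lasso", c(f1, f2))
      a
    }
  })

  run_stage("network", {
    kn <- sim$knowledge
    pm <- data.frame(protein_id = mapped$mapping$protein_id,
                     metabolite_id = mapped$mapping$measured_id,
                     source = mapped$mapping$source)
    pm <- pm[pm$source != "pathway", , drop = FALSE]
    if (nrow(pm)) {
      g <- interaction_graph(unique(pm), kn$ppi_edges)
      ranked <- records[order(records$p_adj, -abs(records$r),
                              records$protein_id, records$metabolite_id), ]
      dd <- shortest_hop_distances(
        g, ranked[, c("protein_id", "metabolite_id")])
      ranked$distance <- dd$distance
      enr <- topk_hop_enrichment(ranked, pmin(k_grid, nrow(ranked)))
      f <- file.path(rc$out_dir, "hop_enrichment.tsv")
      write_tsv_table(enr, f)
      stage_files("network", f)
    } else {
      manifest$warnings <<- c(manifest$warnings,
                              "no protein-metabolite reference edges; hop analysis skipped")
    }
    NULL
  })

  run_stage("evaluate", {
    truth <- sim$truth_edges
    if (!is.null(truth) && nrow(truth) && !is.null(assoc)) {
      key <- function(p, m) paste(p, m, sep = "\r")
      truth_keys <- key(truth$protein_id, truth$metabolite_id)
      uni <- key(records$protein_id, records$metabolite_id)
      pairwise <- data.frame(pair_id = uni, score = records$p_adj,
                             label = uni %in% truth_keys)
      lscore <- stats::setNames(rep(1, length(uni)), uni)
      akey <- key(assoc$protein_id, assoc$metabolite_id)
      lscore[akey[akey %in% uni]] <- assoc$fdr_q[akey %in% uni]
      lasso_scored <- data.frame(pair_id = uni, score = unname(lscore[uni]),
                                 label = uni %in% truth_keys)
      cmp <- compare_methods(pairwise, lasso_scored,
                             n_boot = rc$n_boot %||% 200)
      jsonlite::write_json(
        list(auc_pairwise = cmp$pairwise$auc, auc_lasso = cmp$lasso$auc,
             delta_auc = cmp$delta_auc, delta_ap = cmp$delta_ap,
             ci_delta_auc = cmp$ci_delta_auc),
        file.path(rc$out_dir, "evaluation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    NULL
  })

  manifest$config <- rc[setdiff(names(rc), "out_dir")]
  if (!is.null(manifest$config$simulate$planted))
    manifest$config$simulate$planted <-
      lapply(manifest$config$simulate$planted, unclass)
  cfg_file <- file.path(rc$out_dir, "run_config.json")
  jsonlite::write_json(manifest$config, cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  manifest$version <- as.character(utils::packageVersion("pmcov"))
  jsonlite::write_json(manifest, file.path(rc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
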