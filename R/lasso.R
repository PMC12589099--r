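#' LASSO configuration
#'
#' Settings for penalized nomination of protein predictors of metabolite
#' abundance. Defaults follow common cohort practice: a fixed master seed
#' for reproducibility, a 90/10 train/validation split, squared-error
#' cross-validation with the 1-SE rule, relaxed-fit mixing over gamma in
#' {0, 0.25, 0.5, 0.75, 1}, unit observation weights, and internal
#' predictor standardization (the data themselves are not pre-scaled;
#' coefficients are reported on the original log2 scale).
#'
#' @param seed Master seed (default 1e8) driving the split and fold
#'   assignment.
#' @param train_fraction Fraction of samples used for modelling
#'   (default 0.9); the remainder validates the fit.
#' @param relax_gammas Relaxed-fit mixing values.
#' @param lambda_rule Only `"1se"` is implemented: the most regularized
#'   model within one standard error of the minimum CV error.
#' @param standardize_internally Standardize predictors inside the
#'   solver.
#' @param cv_folds Number of CV folds (default 10).
#' @param min_samples Minimum complete-case samples required per
#'   metabolite (default 30).
#' @param max_protein_missing Proteins missing in more than this fraction
#'   of samples are dropped from the design; remaining missing entries
#'   are mean-imputed (default 0.1).
#' @return A `lasso_config` list.
#' @export
lasso_config <- function(seed = 1e8, train_fraction = 0.9,
                         relax_gammas = c(0, 0.25, 0.5, 0.75, 1),
                         lambda_rule = "1se",
                         standardize_internally = TRUE,
                         cv_folds = 10, min_samples = 30,
                         max_protein_missing = 0.1) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            all(relax_gammas >= 0 & relax_gammas <= 1),
            identical(lambda_rule, "1se"), cv_folds >= 3)
  structure(list(seed = seed, train_fraction = train_fraction,
                 relax_gammas = relax_gammas, lambda_rule = lambda_rule,
                 standardize_internally = standardize_internally,
                 cv_folds = as.integer(cv_folds),
                 min_samples = as.integer(min_samples),
                 max_protein_missing = max_protein_missing),
            class = "lasso_config")
}

# Complete-case design for one metabolite: samples with the metabolite
# observed; proteins above the missingness ceiling dropped; remaining
# missing protein entries mean-imputed.
prepare_design <- function(protein_matrix, metabolite_vector, config) {
  keep_s <- !is.na(metabolite_vector)
  x <- protein_matrix[keep_s, , drop = FALSE]
  y <- metabolite_vector[keep_s]
  miss <- colMeans(is.na(x))
  x <- x[, miss <= config$max_protein_missing, drop = FALSE]
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  list(x = x, y = y)
}

#' Fit a relaxed LASSO for one metabolite
#'
#' Regresses a metabolite's log2 abundance on the full protein matrix with
#' an L1 penalty. The samples are split into a training fraction (for the
#' cross-validated path) and a holdout (on which predicted abundance is
#' correlated with measured abundance). The (gamma, lambda) pair is chosen
#' by minimum CV error over the relaxed paths, then the 1-SE rule is
#' applied along the chosen gamma's path, yielding the most regularized
#' acceptable model. Nonzero coefficients are the nominated predictors.
#'
#' @param protein_matrix Individuals x proteins matrix (log2 scale).
#' @param metabolite_vector Numeric vector aligned to rows, NA = missing.
#' @param config A [lasso_config()].
#' @param metabolite_id,tissue Labels stored on the fit.
#' @param seed_offset Stream index mixed into the master seed so a run
#'   over many metabolites draws independent splits; offset 0 reproduces
#'   the same fit for the same inputs.
#' @return A `lasso_fit` list: `selected` (named nonzero coefficients),
#'   `chosen_gamma`, `chosen_lambda`, `holdout_r`, `n_train`, `n_test`.
#' @export
fit_metabolite_lasso <- function(protein_matrix, metabolite_vector, config,
                                 metabolite_id = "metabolite",
                                 tissue = "tissue", seed_offset = 0) {
  d <- prepare_design(protein_matrix, metabolite_vector, config)
  n <- length(d$y)
  if (n < config$min_samples)
    stop("fewer than ", config$min_samples, " complete-case samples for ",
         metabolite_id)
  if (stats::sd(d$y) == 0) stop("all-constant metabolite: ", metabolite_id)

  set.seed(derive_seed(config$seed, seed_offset))
  n_test <- max(1L, round((1 - config$train_fraction) * n))
  test_idx <- sample.int(n, n_test)
  train_idx <- setdiff(seq_len(n), test_idx)
  foldid <- sample(rep_len(seq_len(config$cv_folds), length(train_idx)))

  cv <- glmnet::cv.glmnet(d$x[train_idx, , drop = FALSE], d$y[train_idx],
                          weights = rep(1, length(train_idx)),
                          foldid = foldid, relax = TRUE,
                          gamma = config$relax_gammas,
                          standardize = config$standardize_internally,
                          family = "gaussian", type.measure = "mse")
  sel <- choose_gamma_lambda(cv)
  beta <- stats::coef(cv$glmnet.fit, s = sel$lambda, gamma = sel$gamma)
  beta <- as.matrix(beta)[-1, 1]             # drop intercept
  selected <- beta[beta != 0]

  holdout_r <- NA_real_
  if (length(selected)) {
    pred <- as.numeric(stats::predict(cv$glmnet.fit,
                                      newx = d$x[test_idx, , drop = FALSE],
                                      s = sel$lambda, gamma = sel$gamma))
    if (stats::sd(pred) > 0 && stats::sd(d$y[test_idx]) > 0)
      holdout_r <- stats::cor(pred, d$y[test_idx])
  }
  structure(list(metabolite_id = metabolite_id, tissue = tissue,
                 selected = selected, chosen_gamma = sel$gamma,
                 chosen_lambda = sel$lambda, holdout_r = holdout_r,
                 n_train = length(train_idx), n_test = n_test),
            class = "lasso_fit")
}

# Minimum CV error over all (gamma, lambda), then the 1-SE rule along the
# winning gamma's path: the largest lambda whose CV error is within one
# standard error of the minimum.
choose_gamma_lambda <- function(cv) {
  stats <- cv$relaxed$statlist
  gammas <- cv$relaxed$gamma
  best <- list(err = Inf)
  for (i in seq_along(stats)) {
    j <- which.min(stats[[i]]$cvm)
    if (stats[[i]]$cvm[j] < best$err)
      best <- list(err = stats[[i]]$cvm[j], sd = stats[[i]]$cvsd[j], i = i)
  }
  path <- stats[[best$i]]
  ok <- path$cvm <= best$err + best$sd
  list(gamma = gammas[best$i], lambda = max(path$lambda[ok]))
}

#' Nominate protein predictors for every metabolite in a tissue
#'
#' Runs [fit_metabolite_lasso()] per metabolite column, skipping (with a
#' message) metabolites with too few complete-case samples or no
#' variance.
#'
#' @param protein_matrix,metabolite_matrix Individuals x features
#'   matrices sharing the sample axis.
#' @param config A [lasso_config()].
#' @param tissue Tissue label.
#' @return List of `lasso_fit` objects, named by metabolite.
#' @export
nominate_predictors <- function(protein_matrix, metabolite_matrix, config,
                                tissue = "tissue") {
  fits <- list()
  for (j in seq_len(ncol(metabolite_matrix))) {
    mid <- colnames(metabolite_matrix)[j]
    fit <- tryCatch(
      fit_metabolite_lasso(protein_matrix, metabolite_matrix[, j], config,
                           metabolite_id = mid, tissue = tissue,
                           seed_offset = j),
      error = function(e) {
        message("skipping ", mid, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) fits[[mid]] <- fit
  }
  fits
}

#' Post-selection FDR by ordinary least squares refit
#'
#' For each metabolite, refits an unpenalized OLS of the metabolite on its
#' LASSO-selected proteins (complete-case samples, same design policy as
#' the penalized fit); each coefficient's two-sided t-test p-value becomes
#' the association's `ols_p`. BH correction is applied globally per tissue
#' over all (protein, metabolite) associations; `fdr_q < alpha` flags
#' global significance. Aliased columns in a rank-deficient selected
#' design are dropped with p = 1.
#'
#' @param fits List of `lasso_fit` (one tissue or several).
#' @param protein_matrices,metabolite_matrices Named lists (by tissue) of
#'   matrices, or single matrices when all fits share one tissue.
#' @param config The [lasso_config()] used for the fits.
#' @param alpha Global FDR level (default 0.05).
#' @return data.frame(tissue, protein_id, metabolite_id, coefficient,
#'   abs_rank, ols_p, fdr_q, globally_significant); `abs_rank` orders a
#'   metabolite's predictors by |coefficient| (1 = largest).
#' @export
post_selection_fdr <- function(fits, protein_matrices, metabolite_matrices,
                               config = lasso_config(), alpha = 0.05) {
  if (!length(fits)) stop("no fits supplied")
  if (is.matrix(protein_matrices)) {
    tiss <- unique(vapply(fits, `[[`, "", "tissue"))
    stopifnot(length(tiss) == 1)
    protein_matrices <- stats::setNames(list(protein_matrices), tiss)
    metabolite_matrices <- stats::setNames(list(metabolite_matrices), tiss)
  }
  rows <- list()
  for (fit in fits) {
    if (!length(fit$selected)) next
    P <- protein_matrices[[fit$tissue]]
    y <- metabolite_matrices[[fit$tissue]][, fit$metabolite_id]
    d <- prepare_design(P, y, config)
    sel <- names(fit$selected)
    x <- d$x[, sel, drop = FALSE]
    colnames(x) <- paste0("v", seq_along(sel))   # safe, unambiguous names
    lmfit <- stats::lm(.y ~ ., data = data.frame(.y = d$y, x))
    sm <- summary(lmfit)$coefficients
    p <- stats::setNames(rep(1, length(sel)), sel)  # aliased -> 1
    got <- intersect(colnames(x), rownames(sm))
    p[match(got, colnames(x))] <- sm[got, "Pr(>|t|)"]
    if (length(got) < length(sel))
      message(fit$metabolite_id, ": ", length(sel) - length(got),
              " aliased predictor(s) dropped, p set to 1")
    ord <- order(-abs(fit$selected))
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = fit$tissue, protein_id = sel,
      metabolite_id = fit$metabolite_id,
      coefficient = unname(fit$selected),
      abs_rank = match(seq_along(sel), ord),
      ols_p = clamp_p(unname(p)), row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(tissue = character(), protein_id = character(),
                      metabolite_id = character(), coefficient = numeric(),
                      abs_rank = integer(), ols_p = numeric(),
                      fdr_q = numeric(), globally_significant = logical()))
  assoc <- do.call(rbind, rows)
  assoc$fdr_q <- NA_real_
  for (t in unique(assoc$tissue)) {
    i <- assoc$tissue == t
    assoc$fdr_q[i] <- bh_adjust(assoc$ols_p[i])
  }
  assoc$globally_significant <- assoc$fdr_q < alpha
  assoc
}

#' Flag extreme-outlier LASSO coefficients
#'
#' Within each tissue, pools all LASSO coefficients, computes Q1 and Q3
#' under the linear-interpolation quartile convention, and flags
#' coefficients lying strictly beyond Q1 - 3*IQR or Q3 + 3*IQR.
#'
#' @param associations Output of [post_selection_fdr()].
#' @return The associations with a logical `extreme_outlier` column.
#' @export
flag_extreme_outliers <- function(associations) {
  associations$extreme_outlier <- FALSE
  for (t in unique(associations$tissue)) {
    i <- associations$tissue == t
    v <- associations$coefficient[i]
    if (sum(i) < 4) {
      message("tissue ", t, ": fewer than 4 coefficients; no outlier call")
      next
    }
    q <- quartiles_type7(v)
    iqr <- q[2] - q[1]
    if (iqr == 0)
      message("tissue ", t, ": zero IQR; only values off the common quartile flag")
    associations$extreme_outlier[i] <-
      v < q[1] - 3 * iqr | v > q[2] + 3 * iqr
  }
  associations
}

#' Validation scores for metabolites
#'
#' Ranks metabolites per tissue by the number of their nominated
#' predictors carrying literature evidence (a mapped reference edge), and
#' linearly rescales that count to a 1-10 score: zero-evidence metabolites
#' (with at least one predictor) score 1, the maximum-evidence metabolite
#' scores 10. The overall score sums across tissues; metabolites absent
#' from a tissue contribute 0 there.
#'
#' @param associations Output of [post_selection_fdr()].
#' @param evidence_edges data.frame(protein_id, measured_id) of
#'   literature-evidenced protein-metabolite pairs (the `mapping` of
#'   [restrict_to_measured()]).
#' @return data.frame(metabolite_id, tissue, evidence_count, score) plus
#'   an `overall` attribute-free summary: one row per metabolite-tissue,
#'   with overall scores obtainable via [validation_score_overall()].
#' @export
compute_validation_scores <- function(associations, evidence_edges) {
  ev_keys <- unique(paste(evidence_edges$protein_id,
                          evidence_edges$measured_id, sep = "\r"))
  out <- list()
  for (t in unique(associations$tissue)) {
    sub <- associations[associations$tissue == t, , drop = FALSE]
    mets <- unique(sub$metabolite_id)
    count <- vapply(mets, function(m) {
      preds <- sub$protein_id[sub$metabolite_id == m]
      sum(paste(preds, m, sep = "\r") %in% ev_keys)
    }, 1L)
    mx <- if (length(count)) max(count) else 0L
    score <- if (mx == 0) rep(1, length(count)) else 1 + 9 * count / mx
    out[[t]] <- data.frame(metabolite_id = mets, tissue = t,
                           evidence_count = count, score = score,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Overall validation score per metabolite
#'
#' Sums a metabolite's per-tissue validation scores across tissues.
#' @param scores Output of [compute_validation_scores()].
#' @return data.frame(metabolite_id, overall), sorted decreasing.
#' @export
validation_score_overall <- function(scores) {
  agg <- stats::aggregate(score ~ metabolite_id, data = scores, FUN = sum)
  names(agg)[2] <- "overall"
  agg[order(-agg$overall), ]
}

#' Annotate nominated associations with functional evidence
#'
#' Each nominated (protein, metabolite) association is checked against the
#' mapped reference edges: a direct reaction edge gives evidence
#' `physical`, a pathway edge `local_pathway`, a transporter edge
#' `transporter`. A predictor with no direct edge but with a physical
#' interactor that is a known local regulator of the metabolite is
#' annotated as mediated: "May act through {mediator} and {pathways}" —
#' the substrate-adaptor pattern in which an unannotated protein controls
#' a metabolite via the enzyme it binds. Class flags record membership in
#' the supplied enzyme/transporter/mitochondrial lists.
#'
#' @param associations Output of [post_selection_fdr()].
#' @param knowledge A `reference_knowledge` list (or any list with
#'   `reaction_edges`, `transporter_edges`, `pathway_memberships`,
#'   `ppi_edges`, `ontology`, `identity`, `class_lists`).
#' @param excluded_top_levels Passed to [ancestor_closure()].
#' @return The associations with columns `evidence`, `mediator`,
#'   `mediator_pathways`, `annotation`, and logical class-flag columns
#'   `is_metabolic_enzyme`, `is_transporter`, `is_mitochondrial`.
#' @export
annotate_associations <- function(associations, knowledge,
                                  excluded_top_levels = 6) {
  edges <- build_reference_edges(knowledge$reaction_edges,
                                 knowledge$transporter_edges,
                                 knowledge$pathway_memberships)
  mapped <- restrict_to_measured(
    edges, unique(c(associations$protein_id, edges$protein_id)),
    knowledge$identity, knowledge$ontology, excluded_top_levels)$mapping
  direct_key <- paste(mapped$protein_id, mapped$measured_id, sep = "\r")
  ppi <- rbind(
    stats::setNames(knowledge$ppi_edges[, c("protein_a", "protein_b")],
                    c("a", "b")),
    stats::setNames(knowledge$ppi_edges[, c("protein_b", "protein_a")],
                    c("a", "b")))
  partners <- split(ppi$b, ppi$a)
  pw <- knowledge$pathway_memberships
  cl <- knowledge$class_lists

  n <- nrow(associations)
  evidence <- rep("none", n)
  mediator <- rep(NA_character_, n)
  med_pw <- rep(NA_character_, n)
  annotation <- rep("", n)
  for (i in seq_len(n)) {
    prot <- associations$protein_id[i]
    met <- associations$metabolite_id[i]
    mine <- mapped[direct_key == paste(prot, met, sep = "\r"), , drop = FALSE]
    if (nrow(mine)) {
      src <- mine$source
      evidence[i] <- if ("reaction" %in% src) "physical"
        else if ("transporter" %in% src) "transporter" else "local_pathway"
      next
    }
    meds <- intersect(unique(partners[[prot]]),
                      mapped$protein_id[mapped$measured_id == met])
    if (length(meds)) {
      m1 <- meds[1]
      # pathways containing the mediator and an ontology node of the metabolite
      met_nodes <- mapped$metabolite_node[mapped$measured_id == met &
                                            mapped$protein_id == m1]
      pws <- unique(pw$pathway_id[pw$member_id == m1])
      pws <- pws[vapply(pws, function(id)
        any(pw$member_id[pw$pathway_id == id] %in% met_nodes), TRUE)]
      mediator[i] <- m1
      med_pw[i] <- paste(pws, collapse = ";")
      annotation[i] <- paste0("May act through ", m1,
                              if (length(pws)) paste0(" and ",
                                paste(pws, collapse = ";")) else "")
    }
  }
  associations$evidence <- evidence
  associations$mediator <- mediator
  associations$mediator_pathways <- med_pw
  associations$annotation <- annotation
  associations$is_metabolic_enzyme <-
    associations$protein_id %in% (cl$metabolic_enzyme %||% character())
  associations$is_transporter <-
    associations$protein_id %in% (cl$transporter %||% character())
  associations$is_mitochondrial <-
    associations$protein_id %in% (cl$mitochondrial %||% character())
  associations
}

#' Proteins predicting multiple metabolites
#'
#' Groups associations by protein and reports those nominated for at
#' least `k` metabolites, sorted by breadth — the pattern in which one
#' protein is an (often outlying) predictor of a family of related
#' metabolites.
#'
#' @param associations Output of [post_selection_fdr()].
#' @param k Minimum number of distinct metabolites (default 2).
#' @return data.frame(protein_id, n_metabolites, metabolite_ids).
#' @export
multi_metabolite_predictors <- function(associations, k = 2) {
  if (!nrow(associations))
    return(data.frame(protein_id = character(), n_metabolites = integer(),
                      metabolite_ids = character()))
  byprot <- split(associations$metabolite_id, associations$protein_id)
  mets <- lapply(byprot, unique)
  breadth <- lengths(mets)
  keep <- breadth >= k
  out <- data.frame(protein_id = names(mets)[keep],
                    n_metabolites = unname(breadth[keep]),
                    metabolite_ids = vapply(mets[keep], paste,
                                            "", collapse = ";"))
  out[order(-out$n_metabolites, out$protein_id), , drop = FALSE]
}
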