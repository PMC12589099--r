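#' All pairwise protein-metabolite Pearson correlations
#'
#' Computes, for every (protein, metabolite) pair sharing a tissue, the
#' Pearson product-moment correlation over pairwise-complete samples and
#' the two-sided p-value from the t distribution with `n_obs - 2` degrees
#' of freedom. Pairs with fewer than `min_obs` complete observations, or
#' with zero variance on the overlap, are omitted (the latter with a
#' message naming the constant feature).
#'
#' @param proteins,metabolites Numeric matrices, individuals x features,
#'   log2 relative abundance, sharing rownames (sample IDs). `NA` =
#'   missing.
#' @param min_obs Minimum pairwise-complete sample count (default 20;
#'   must be >= 3).
#' @param tissue Tissue label stored on every record.
#' @return data.frame(tissue, protein_id, metabolite_id, n_obs, r, p,
#'   p_adj, significant, sign_class); `p_adj`, `significant` and
#'   `sign_class` are filled by [adjust_bh()].
#' @examples
#' p <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("P1", "P2")))
#' m <- cbind(M1 = p[, 1] * 2 + 3)
#' correlate_all(p, m, min_obs = 10, tissue = "liver")
#' @export
correlate_all <- function(proteins, metabolites, min_obs = 20,
                          tissue = "tissue") {
  stopifnot(min_obs >= 3, nrow(proteins) == nrow(metabolites))
  if (!is.null(rownames(proteins)) && !is.null(rownames(metabolites)) &&
      !identical(rownames(proteins), rownames(metabolites)))
    stop("protein and metabolite matrices must share the sample axis")
  prot_ids <- colnames(proteins) %||% paste0("P", seq_len(ncol(proteins)))
  met_ids <- colnames(metabolites) %||% paste0("M", seq_len(ncol(metabolites)))

  P <- proteins
  obsP <- !is.na(P)
  P[!obsP] <- 0
  out <- vector("list", ncol(metabolites))
  for (j in seq_len(ncol(metabolites))) {
    y <- metabolites[, j]
    w <- !is.na(y)
    yv <- ifelse(w, y, 0)
    V <- obsP & w                      # per-entry joint observation
    n <- colSums(V)
    Pw <- P * w                        # zero where y missing or P missing
    sx <- colSums(Pw)
    sxx <- colSums(Pw * P)
    sy <- colSums(V * yv)
    syy <- colSums(V * yv^2)
    sxy <- colSums(P * yv)
    vx <- n * sxx - sx^2
    vy <- n * syy - sy^2
    keep <- n >= min_obs
    zerovar <- keep & (vx <= 0 | vy <= 0)
    if (any(zerovar))
      message("constant feature on overlap; omitting ",
              sum(zerovar), " pair(s) for ", met_ids[j])
    keep <- keep & !zerovar
    if (!any(keep)) next
    r <- (n[keep] * sxy[keep] - sx[keep] * sy[keep]) /
      sqrt(vx[keep] * vy[keep])
    r <- pmin(1, pmax(-1, r))
    df <- n[keep] - 2
    tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
    p <- clamp_p(2 * stats::pt(abs(tt), df, lower.tail = FALSE))
    out[[j]] <- data.frame(tissue = tissue,
                           protein_id = prot_ids[keep],
                           metabolite_id = met_ids[j],
                           n_obs = n[keep], r = r, p = p,
                           p_adj = NA_real_, significant = NA,
                           sign_class = NA_character_,
                           row.names = NULL)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(tissue = character(), protein_id = character(),
                      metabolite_id = character(), n_obs = integer(),
                      r = numeric(), p = numeric(), p_adj = numeric(),
                      significant = logical(), sign_class = character()))
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment and sign classification of correlations
#'
#' Applies the BH step-up procedure within the stated family and fills
#' `p_adj`, `significant` (`p_adj < alpha`) and `sign_class`:
#' co-operative for significant positive r, antagonistic for significant
#' negative r, none otherwise.
#'
#' @param records Output of [correlate_all()] (possibly row-bound across
#'   tissues).
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @param family `"per_tissue"` (default): adjust within each tissue;
#'   `"pooled"`: one family across all records.
#' @return The records with `p_adj`, `significant`, `sign_class` filled.
#' @export
adjust_bh <- function(records, alpha = 0.05, family = c("per_tissue", "pooled")) {
  family <- match.arg(family)
  stopifnot(alpha > 0, alpha < 1)
  if (!nrow(records)) return(records)
  if (family == "per_tissue") {
    for (t in unique(records$tissue)) {
      i <- records$tissue == t
      records$p_adj[i] <- bh_adjust(records$p[i])
    }
  } else {
    records$p_adj <- bh_adjust(records$p)
  }
  records$significant <- records$p_adj < alpha
  records$sign_class <- ifelse(!records$significant, "none",
                               ifelse(records$r > 0, "co-operative",
                                      "antagonistic"))
  records
}

#' Count significant covariation pairs by sign class
#'
#' Per-tissue counts of co-operative (significant, r > 0) and antagonistic
#' (significant, r < 0) pairs, plus a pooled summary in which a
#' (protein, metabolite) pair significant in several tissues is counted
#' once in the non-redundant unique total but once per tissue in the sign
#' classes.
#'
#' @param records Records after [adjust_bh()].
#' @return list(per_tissue = data.frame(tissue, n_significant,
#'   n_cooperative, n_antagonistic), pooled = list(
#'   n_significant_unique_pairs, n_cooperative, n_antagonistic)).
#' @export
classify_cooperativity <- function(records) {
  sig <- records[which(records$significant), , drop = FALSE]
  tissues <- unique(records$tissue)
  per <- do.call(rbind, lapply(tissues, function(t) {
    s <- sig[sig$tissue == t, , drop = FALSE]
    data.frame(tissue = t, n_significant = nrow(s),
               n_cooperative = sum(s$sign_class == "co-operative"),
               n_antagonistic = sum(s$sign_class == "antagonistic"))
  })) %||% data.frame(tissue = character(), n_significant = integer(),
                      n_cooperative = integer(), n_antagonistic = integer())
  pooled <- list(
    n_significant_unique_pairs =
      length(unique(paste(sig$protein_id, sig$metabolite_id, sep = "\r"))),
    n_cooperative = sum(sig$sign_class == "co-operative"),
    n_antagonistic = sum(sig$sign_class == "antagonistic"))
  list(per_tissue = per, pooled = pooled)
}

#' Flag contaminant proteins by principal-component loading
#'
#' Identifies a contamination signature the way cross-tissue carry-over is
#' screened in cohort proteomics: features whose PC1 loading (computed on
#' the complete-case submatrix, since the decomposition does not admit
#' missing values) falls in the top `loading_quantile` by absolute value
#' AND belong to a supplied signature set (e.g. muscle-specific proteins)
#' are removed, together with any feature — including features with
#' missing values — whose pairwise-complete Pearson correlation with a
#' removed signature feature exceeds `corr_threshold`.
#'
#' @param matrix_ Individuals x proteins matrix (log2 scale, NA allowed).
#' @param signature Character vector of suspect protein IDs.
#' @param loading_quantile Top fraction of |PC1 loading| examined
#'   (default 0.025).
#' @param corr_threshold Pearson r above which a feature is dragged along
#'   with a removed signature feature (default 0.9).
#' @return list(removed_feature_ids, pc1_loading (named, complete-case
#'   features only), removal_reason — named character of
#'   "signature_overlap"/"correlated_with_removed").
#' @export
flag_contaminant_proteins <- function(matrix_, signature,
                                      loading_quantile = 0.025,
                                      corr_threshold = 0.9) {
  complete <- colSums(is.na(matrix_)) == 0
  if (sum(complete) < 2) stop("fewer than 2 complete-case features for PCA")
  pc <- stats::prcomp(matrix_[, complete, drop = FALSE],
                      center = TRUE, scale. = FALSE)
  loading <- pc$rotation[, 1]
  if (!any(colnames(matrix_) %in% signature)) {
    warning("signature proteins absent from matrix; nothing removed")
    return(list(removed_feature_ids = character(),
                pc1_loading = loading,
                removal_reason = character()))
  }
  cutoff <- stats::quantile(abs(loading), 1 - loading_quantile, type = 7)
  top <- names(loading)[abs(loading) >= cutoff]
  core <- intersect(top, signature)
  reason <- stats::setNames(rep("signature_overlap", length(core)), core)
  if (length(core)) {
    others <- setdiff(colnames(matrix_), core)
    cc <- suppressWarnings(
      stats::cor(matrix_[, others, drop = FALSE],
                 matrix_[, core, drop = FALSE],
                 use = "pairwise.complete.obs"))
    dragged <- others[apply(cc, 1, function(z) any(z > corr_threshold, na.rm = TRUE))]
    reason <- c(reason, stats::setNames(
      rep("correlated_with_removed", length(dragged)), dragged))
  }
  list(removed_feature_ids = names(reason),
       pc1_loading = loading,
       removal_reason = reason)
}

#' Coefficient of variation per feature
#'
#' Population CV (standard deviation with the 1/N divisor, divided by the
#' mean) over non-missing entries, computed on the linear ratio scale.
#' Callers holding log2 data back-transform first (`linearize = TRUE`
#' applies `2^x` before computing).
#'
#' @param ratio_matrix Individuals x features matrix of positive ratios
#'   (or log2 ratios with `linearize = TRUE`).
#' @param linearize Back-transform log2 values with `2^x` first.
#' @return Named numeric vector of CVs.
#' @examples
#' feature_cv(cbind(f = c(1, 2, 3)))            # sqrt(2/3)/2
#' feature_cv(cbind(f = c(0, 1)), linearize = TRUE) # 0.5/1.5
#' @export
feature_cv <- function(ratio_matrix, linearize = FALSE) {
  x <- if (linearize) 2^ratio_matrix else ratio_matrix
  if (any(x <= 0, na.rm = TRUE)) stop("ratios must be positive on the linear scale")
  apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    mu <- mean(v)
    if (mu == 0) return(NaN)
    sqrt(mean((v - mu)^2)) / mu
  })
}
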