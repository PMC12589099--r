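#' Planted protein-metabolite relationships
#'
#' Constructors for the relationships a synthetic cohort plants into its
#' abundance matrices. Effects are linear on the log2 scale: a slope `beta`
#' of 1 means a doubling of the upstream protein doubles the metabolite.
#'
#' `planted_enzyme()` and `planted_transporter()` plant a direct
#' protein -> metabolite effect. `planted_adaptor_chain()` plants a
#' two-step chain: the adaptor sets the effective activity of an enzyme
#' (think substrate adaptors that control enzyme degradation), and the
#' metabolite responds to that activity; the enzyme's measured abundance
#' is a noisy readout of the activity, so the adaptor carries predictive
#' information beyond the measured enzyme, as in real post-translational
#' regulation. `planted_null()` plants a metabolite of pure noise, an
#' explicit negative control pair.
#'
#' @param protein,adaptor,enzyme Integer feature indices into the protein
#'   axis (1-based).
#' @param metabolite Integer index into the metabolite axis.
#' @param beta Signed effect size (log2-per-log2 slope).
#' @param beta_adaptor,beta_enzyme Slopes of the adaptor -> enzyme-activity
#'   and enzyme-activity -> metabolite steps.
#' @return A `planted_relationship` list.
#' @examples
#' planted_enzyme(protein = 1, metabolite = 1, beta = 1)
#' planted_adaptor_chain(adaptor = 2, enzyme = 3, metabolite = 2,
#'                       beta_adaptor = -1, beta_enzyme = 1)
#' @name planted
NULL

new_planted <- function(kind, protein_ids, metabolite_id, effect_size) {
  stopifnot(all(is.finite(effect_size)))
  structure(list(kind = kind,
                 protein_ids = as.integer(protein_ids),
                 metabolite_id = as.integer(metabolite_id),
                 effect_size = as.numeric(effect_size)),
            class = "planted_relationship")
}

#' @rdname planted
#' @export
planted_enzyme <- function(protein, metabolite, beta) {
  new_planted("enzyme_direct", protein, metabolite, beta)
}

#' @rdname planted
#' @export
planted_transporter <- function(protein, metabolite, beta) {
  new_planted("transporter", protein, metabolite, beta)
}

#' @rdname planted
#' @export
planted_adaptor_chain <- function(adaptor, enzyme, metabolite,
                                  beta_adaptor, beta_enzyme) {
  new_planted("adaptor_chain", c(adaptor, enzyme), metabolite,
              c(beta_adaptor, beta_enzyme))
}

#' @rdname planted
#' @export
planted_null <- function(protein, metabolite) {
  new_planted("null_pair", protein, metabolite, 0)
}

#' Configuration of a synthetic multi-omic cohort
#'
#' Defines a cohort of genetically diverse individuals profiled for
#' protein and metabolite abundance in one or more tissues. Defaults
#' emulate a diversity-outbred mouse cohort: 163 individuals, thousands of
#' proteins, on the order of a hundred metabolites per tissue, log2
#' relative abundances (sample/reference ratios), a latent-factor model of
#' shared genetic variation, and a small completely-at-random missing
#' fraction reflecting the high data completeness of isobaric-label
#' proteomics.
#'
#' @param n_individuals Number of individuals (>= 3).
#' @param n_proteins,n_metabolites Feature counts per tissue.
#' @param n_latent_factors Number of latent (genetic) factors inducing
#'   protein-protein covariance.
#' @param planted List of [planted_relationship][planted] objects.
#' @param noise_sd_protein,noise_sd_metabolite Gaussian noise SD in log2
#'   units added per feature.
#' @param latent_sd_protein,latent_sd_metabolite SD of the latent
#'   (shared, genetic) component per feature. The defaults give proteins
#'   half shared and half independent variance at a total log2 SD of
#'   about 0.7, in line with reported proteome heritability and
#'   cohort-scale ratio spreads, and metabolites a smaller heritable
#'   share; features are co-regulated but planted effects stay
#'   identifiable.
#' @param missing_rate Fraction of entries set missing, uniformly at
#'   random, per matrix; must leave every feature with >= 3 observations.
#' @param seed Master integer seed; one RNG stream per tissue is derived
#'   from it so adding a tissue does not perturb existing tissues.
#' @param tissue_labels Character vector of tissue names.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_individuals = 163,
                          n_proteins = 2000,
                          n_metabolites = 100,
                          n_latent_factors = 10,
                          planted = list(),
                          noise_sd_protein = 0.5,
                          noise_sd_metabolite = 0.5,
                          latent_sd_protein = 0.5,
                          latent_sd_metabolite = 0.3,
                          missing_rate = 0.02,
                          seed = 1,
                          tissue_labels = c("BAT", "liver")) {
  cfg <- structure(list(n_individuals = as.integer(n_individuals),
                        n_proteins = as.integer(n_proteins),
                        n_metabolites = as.integer(n_metabolites),
                        n_latent_factors = as.integer(n_latent_factors),
                        planted = planted,
                        noise_sd_protein = noise_sd_protein,
                        noise_sd_metabolite = noise_sd_metabolite,
                        latent_sd_protein = latent_sd_protein,
                        latent_sd_metabolite = latent_sd_metabolite,
                        missing_rate = missing_rate,
                        seed = as.integer(seed),
                        tissue_labels = tissue_labels),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_individuals < 3) stop("n_individuals must be >= 3")
  if (cfg$n_proteins < 1 || cfg$n_metabolites < 1 || cfg$n_latent_factors < 1)
    stop("dimensions must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  for (pl in cfg$planted) {
    stopifnot(inherits(pl, "planted_relationship"))
    if (any(pl$protein_ids < 1) || any(pl$protein_ids > cfg$n_proteins))
      stop("planted protein index out of range")
    if (pl$metabolite_id < 1 || pl$metabolite_id > cfg$n_metabolites)
      stop("planted metabolite index out of range")
    if (pl$kind == "adaptor_chain" && length(pl$protein_ids) != 2)
      stop("adaptor_chain must list exactly two proteins (adaptor, enzyme)")
    if (pl$kind == "null_pair" && any(pl$effect_size != 0))
      stop("null_pair must have effect_size 0")
  }
  invisible(cfg)
}

protein_label <- function(i) sprintf("P%04d", i)
metabolite_label <- function(i) sprintf("M%03d", i)

#' Simulate a synthetic cohort
#'
#' Generates, per tissue, an individuals x proteins and an individuals x
#' metabolites matrix of log2 relative abundances. Protein values are
#' latent-factor loadings times per-individual factor scores plus Gaussian
#' noise; planted metabolites are linear responses to their upstream
#' proteins plus noise; unplanted metabolites carry latent-factor
#' background plus noise; null-pair metabolites are pure noise.
#' Missingness is applied last, uniformly at random, per matrix.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_dataset` list with elements `proteins` and
#'   `metabolites` (named lists of matrices, one per tissue; rownames are
#'   sample IDs, colnames feature IDs), `truth_edges` (data.frame of
#'   protein_id, metabolite_id, sign, kind — including induced
#'   adaptor-metabolite edges whose sign composes the chain slopes),
#'   `knowledge` (see [simulate_reference_knowledge()]) and `config`.
#' @examples
#' cfg <- cohort_config(n_individuals = 20, n_proteins = 10,
#'                      n_metabolites = 3, missing_rate = 0,
#'                      planted = list(planted_enzyme(1, 1, beta = 1)),
#'                      tissue_labels = "liver", seed = 7)
#' sim <- simulate_cohort(cfg)
#' dim(sim$proteins$liver)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_individuals
  p <- config$n_proteins
  m <- config$n_metabolites
  k <- config$n_latent_factors

  sample_ids <- sprintf("S%03d", seq_len(n))
  prot_ids <- protein_label(seq_len(p))
  met_ids <- metabolite_label(seq_len(m))

  planted_by_met <- split(config$planted,
                          vapply(config$planted, function(x) x$metabolite_id, 1L))

  proteins <- list()
  metabolites <- list()
  for (ti in seq_along(config$tissue_labels)) {
    tissue <- config$tissue_labels[ti]
    set.seed(derive_seed(config$seed, ti))

    Z <- matrix(stats::rnorm(n * k), n, k)
    L <- matrix(stats::rnorm(p * k, sd = config$latent_sd_protein / sqrt(k)),
                p, k)
    P <- Z %*% t(L) +
      matrix(stats::rnorm(n * p, sd = config$noise_sd_protein), n, p)

    # adaptor chains: enzyme activity driven by the adaptor; the stored
    # enzyme column is a noisy readout of that activity
    activity <- list()
    for (pl in config$planted) {
      if (pl$kind != "adaptor_chain") next
      a <- pl$protein_ids[1]; e <- pl$protein_ids[2]
      act <- pl$effect_size[1] * P[, a] +
        stats::rnorm(n, sd = config$noise_sd_protein)
      P[, e] <- act + stats::rnorm(n, sd = config$noise_sd_protein)
      activity[[length(activity) + 1L]] <- list(enzyme = e, act = act)
      names(activity)[length(activity)] <- chain_key(pl)
    }

    Lm <- matrix(stats::rnorm(m * k, sd = config$latent_sd_metabolite / sqrt(k)),
                 m, k)
    M <- Z %*% t(Lm) +
      matrix(stats::rnorm(n * m, sd = config$noise_sd_metabolite), n, m)
    for (mi in names(planted_by_met)) {
      j <- as.integer(mi)
      val <- stats::rnorm(n, sd = config$noise_sd_metabolite)
      for (pl in planted_by_met[[mi]]) {
        val <- val + switch(pl$kind,
          enzyme_direct = ,
          transporter = pl$effect_size[1] * P[, pl$protein_ids[1]],
          adaptor_chain = pl$effect_size[2] * activity[[chain_key(pl)]]$act,
          null_pair = 0)
      }
      M[, j] <- val
    }

    dimnames(P) <- list(sample_ids, prot_ids)
    dimnames(M) <- list(sample_ids, met_ids)
    if (config$missing_rate > 0) {
      P <- apply_mcar(P, config$missing_rate)
      M <- apply_mcar(M, config$missing_rate)
    }
    proteins[[tissue]] <- P
    metabolites[[tissue]] <- M
  }

  structure(list(proteins = proteins,
                 metabolites = metabolites,
                 truth_edges = truth_edges_of(config),
                 knowledge = simulate_reference_knowledge(config),
                 config = config),
            class = "cohort_dataset")
}

chain_key <- function(pl) paste0("chain_", paste(pl$protein_ids, collapse = "_"),
                                 "_", pl$metabolite_id)

apply_mcar <- function(x, rate) {
  mask <- matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x))
  x[mask] <- NA_real_
  if (any(colSums(!is.na(x)) < 3))
    stop("degenerate feature: missing_rate leaves a feature with < 3 observations")
  x
}

#' Ground-truth edges implied by a cohort configuration
#'
#' Direct edges for every planted enzyme, transporter and chain-enzyme
#' effect, plus the induced adaptor-metabolite edge whose sign is the
#' product of the two chain slopes.
#' @param config A [cohort_config()].
#' @return data.frame(protein_id, metabolite_id, sign, kind).
#' @export
truth_edges_of <- function(config) {
  rows <- list()
  for (pl in config$planted) {
    met <- metabolite_label(pl$metabolite_id)
    if (pl$kind %in% c("enzyme_direct", "transporter")) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_label(pl$protein_ids[1]), metabolite_id = met,
        sign = sign(pl$effect_size[1]), kind = pl$kind)
    } else if (pl$kind == "adaptor_chain") {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_label(pl$protein_ids[2]), metabolite_id = met,
        sign = sign(pl$effect_size[2]), kind = "chain_enzyme")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_label(pl$protein_ids[1]), metabolite_id = met,
        sign = sign(pl$effect_size[1]) * sign(pl$effect_size[2]),
        kind = "chain_adaptor_induced")
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), metabolite_id = character(),
                      sign = numeric(), kind = character()))
  do.call(rbind, rows)
}

#' Simulate reference-knowledge tables matched to a cohort
#'
#' Builds a toy knowledge base consistent with the planted relationships:
#' an ontology in which each measured metabolite has a direct identifier
#' (level 9) under two ancestor class nodes (levels 8 and 7) that hang off
#' a chain of broad top-level nodes (levels 1-6, excluded from ancestor
#' closure by default); reaction and transporter edge tables carrying
#' every planted direct relationship; protein-protein interaction edges
#' carrying each adaptor-enzyme pair (adaptors never appear in reaction
#' edges — they are known only through a physical interactor); pathway
#' memberships grouping each planted enzyme with its metabolite; and named
#' protein class lists.
#'
#' @param config A [cohort_config()].
#' @param decoy_edges Number of decoy reaction edges (random protein x
#'   measured-metabolite pairs not planted) to add.
#' @param decoy_ppi Number of random decoy protein-protein edges.
#' @param indirection Integer 0-2: how many ancestor steps above the
#'   direct identifier planted reaction/transporter edges point at (0 =
#'   direct ID, 2 = the level-7 class node), exercising ancestry mapping.
#' @return A `reference_knowledge` list with data.frames
#'   `reaction_edges` (record_id, protein_id, metabolite_node, role),
#'   `transporter_edges`, `pathway_memberships` (pathway_id, member_id,
#'   member_kind), `ppi_edges` (protein_a, protein_b; undirected),
#'   `ontology` (node_id, parent_id, level), `identity` (measured_id,
#'   node_id) and `class_lists`.
#' @export
simulate_reference_knowledge <- function(config, decoy_edges = 0,
                                         decoy_ppi = 0, indirection = 0) {
  validate_cohort_config(config)
  stopifnot(indirection %in% 0:2)
  m <- config$n_metabolites
  met_ids <- metabolite_label(seq_len(m))

  # broad top levels 1..6 (single chain), excluded from closure by default
  broad <- sprintf("ONT:L%d", 1:6)
  ont <- data.frame(node_id = broad,
                    parent_id = c(NA_character_, broad[-6]),
                    level = 1:6)
  direct <- sprintf("CH:%s", met_ids)
  anc1 <- sprintf("CH:%s:anc1", met_ids)
  anc2 <- sprintf("CH:%s:anc2", met_ids)
  ont <- rbind(ont,
               data.frame(node_id = anc2, parent_id = broad[6], level = 7),
               data.frame(node_id = anc1, parent_id = anc2, level = 8),
               data.frame(node_id = direct, parent_id = anc1, level = 9))
  identity <- data.frame(measured_id = met_ids, node_id = direct)
  target_node <- switch(as.character(indirection),
                        "0" = direct, "1" = anc1, "2" = anc2)

  rx <- list(); tx <- list(); ppi <- list(); pw <- list()
  enzymes <- character(); transporters <- character()
  rec <- 0L
  for (pl in config$planted) {
    if (pl$metabolite_id > m) stop("planted metabolite has no ontology identity")
    node <- target_node[pl$metabolite_id]
    met <- metabolite_label(pl$metabolite_id)
    if (pl$kind == "enzyme_direct") {
      rec <- rec + 1L
      enz <- protein_label(pl$protein_ids[1])
      rx[[length(rx) + 1L]] <- data.frame(record_id = sprintf("RX:%04d", rec),
                                          protein_id = enz,
                                          metabolite_node = node,
                                          role = "substrate")
      enzymes <- c(enzymes, enz)
      pw[[length(pw) + 1L]] <- data.frame(
        pathway_id = sprintf("PW:%04d", rec),
        member_id = c(enz, node), member_kind = c("protein", "metabolite"))
    } else if (pl$kind == "transporter") {
      trp <- protein_label(pl$protein_ids[1])
      tx[[length(tx) + 1L]] <- data.frame(protein_id = trp,
                                          metabolite_node = node)
      transporters <- c(transporters, trp)
    } else if (pl$kind == "adaptor_chain") {
      rec <- rec + 1L
      adaptor <- protein_label(pl$protein_ids[1])
      enz <- protein_label(pl$protein_ids[2])
      rx[[length(rx) + 1L]] <- data.frame(record_id = sprintf("RX:%04d", rec),
                                          protein_id = enz,
                                          metabolite_node = node,
                                          role = "substrate")
      ppi[[length(ppi) + 1L]] <- data.frame(protein_a = adaptor, protein_b = enz)
      enzymes <- c(enzymes, enz)
      pw[[length(pw) + 1L]] <- data.frame(
        pathway_id = sprintf("PW:%04d", rec),
        member_id = c(enz, node), member_kind = c("protein", "metabolite"))
    }
  }
  rx <- if (length(rx)) do.call(rbind, rx) else
    data.frame(record_id = character(), protein_id = character(),
               metabolite_node = character(), role = character())
  tx <- if (length(tx)) do.call(rbind, tx) else
    data.frame(protein_id = character(), metabolite_node = character())
  ppi <- if (length(ppi)) do.call(rbind, ppi) else
    data.frame(protein_a = character(), protein_b = character())
  pw <- if (length(pw)) do.call(rbind, pw) else
    data.frame(pathway_id = character(), member_id = character(),
               member_kind = character())

  set.seed(derive_seed(config$seed, 104729))
  if (decoy_edges > 0) {
    planted_pairs <- paste(rx$protein_id, rx$metabolite_node)
    got <- 0L
    while (got < decoy_edges) {
      pr <- protein_label(sample.int(config$n_proteins, 1))
      mt <- sample.int(m, 1)
      # decoys avoid proteins with any planted role, so truth stays clean
      if (pr %in% c(enzymes, transporters)) next
      key <- paste(pr, target_node[mt])
      if (key %in% planted_pairs) next
      rec <- rec + 1L
      rx <- rbind(rx, data.frame(record_id = sprintf("RX:%04d", rec),
                                 protein_id = pr,
                                 metabolite_node = target_node[mt],
                                 role = "substrate"))
      planted_pairs <- c(planted_pairs, key)
      got <- got + 1L
    }
  }
  if (decoy_ppi > 0) {
    pa <- protein_label(sample.int(config$n_proteins, decoy_ppi, replace = TRUE))
    pb <- protein_label(sample.int(config$n_proteins, decoy_ppi, replace = TRUE))
    keep <- pa != pb
    ppi <- rbind(ppi, data.frame(protein_a = pa[keep], protein_b = pb[keep]))
  }
  mito <- protein_label(sample.int(config$n_proteins,
                                   max(1L, round(0.1 * config$n_proteins))))

  structure(list(reaction_edges = rx,
                 transporter_edges = tx,
                 pathway_memberships = pw,
                 ppi_edges = unique(ppi),
                 ontology = ont,
                 identity = identity,
                 class_lists = list(metabolic_enzyme = unique(enzymes),
                                    transporter = unique(transporters),
                                    mitochondrial = unique(mito))),
            class = "reference_knowledge")
}
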