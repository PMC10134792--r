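#' Deterministic seed splitting
#'
#' All generator randomness flows from one integer seed. Sub-streams are
#' derived by hashing string labels (stage, study, ...) into an offset and
#' adding it to the seed modulo 2^31 - 1, so any sub-generator can be re-run
#' independently and reproducibly.
#'
#' @param seed Integer master seed.
#' @param ... Character labels identifying the sub-stream.
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
split_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.draw_depths <- function(n, depth_mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(depth_mean) - sdlog^2 / 2
  pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
}

.synthetic_phyla <- function(n_features) {
  pool <- c("Firmicutes", "Bacteroidetes", "Actinobacteria", "Proteobacteria")
  probs <- c(0.5, 0.25, 0.15, 0.1)
  sample(pool, n_features, replace = TRUE, prob = probs)
}

.feature_ids <- function(n) sprintf("sp%03d", seq_len(n))

#' Simulate one case-control metagenomic study
#'
#' Generates a compositional count table for responders (R) and nonresponders
#' (NR). Per sample, the composition is
#' `softmax(baseline_logits + group * log_fold + study_bias + sample_noise)`
#' and counts are multinomial at a log-normally distributed depth. Planted
#' effects shift the logit abundance of chosen features in responders,
#' emulating the log-fold differentials the ranking stage estimates.
#'
#' @param n_R,n_NR Number of responder / nonresponder samples.
#' @param n_features Number of species.
#' @param effects Data frame (`feature_id`, `log_fold`) of planted effects,
#'   or `NULL` for a null study.
#' @param depth_mean Mean sequencing depth (log-normal, CV `depth_cv`).
#' @param seed Integer seed; identical seeds give identical output.
#' @param study Study name recorded in metadata and sample ids.
#' @param study_bias_sd SD of the per-study, per-feature logit offset that
#'   emulates DNA-extraction batch effects (default 0.5).
#' @param sample_noise_sd SD of per-sample logit jitter giving overdispersion
#'   relative to pure multinomial sampling (default 0.3).
#' @param depth_cv Coefficient of variation of depth (default 0.3).
#' @param baseline_logits,study_bias Optional named numeric vectors reused
#'   across studies by [generate_multi_study()]; drawn from N(0, 2) and
#'   N(0, `study_bias_sd`) when `NULL`.
#' @return List with `table` ([feature_table()]), `metadata`
#'   ([sample_metadata()]) and `truth` (class `synthetic_truth`).
#' @export
generate_case_control_study <- function(n_R, n_NR, n_features = 200,
                                        effects = NULL, depth_mean = 10000,
                                        seed = 1, study = "study1",
                                        study_bias_sd = 0.5,
                                        sample_noise_sd = 0.3,
                                        depth_cv = 0.3,
                                        baseline_logits = NULL,
                                        study_bias = NULL) {
  stopifnot(n_R > 0, n_NR > 0, n_features > 1)
  ids <- .feature_ids(n_features)
  if (!is.null(effects)) {
    if (nrow(effects) >= n_features) stop("more effects than features")
    unknown <- setdiff(effects$feature_id, ids)
    if (length(unknown)) stop("effect on unknown feature_id: ",
                              paste(unknown, collapse = ", "))
  }
  set.seed(split_seed(seed, "case_control", study))
  phyla <- .synthetic_phyla(n_features)
  if (is.null(baseline_logits)) {
    baseline_logits <- stats::setNames(stats::rnorm(n_features, 0, 2), ids)
    # planted biomarkers sit in the moderately-prevalent range, mirroring the
    # prevalence range of reported consistent biomarkers
    if (!is.null(effects)) {
      baseline_logits[effects$feature_id] <-
        pmax(baseline_logits[effects$feature_id], -1)
    }
  }
  if (is.null(study_bias)) {
    study_bias <- stats::setNames(stats::rnorm(n_features, 0, study_bias_sd), ids)
  }
  log_fold <- stats::setNames(rep(0, n_features), ids)
  if (!is.null(effects)) log_fold[effects$feature_id] <- effects$log_fold

  n <- n_R + n_NR
  group <- c(rep(1, n_R), rep(0, n_NR))
  depths <- .draw_depths(n, depth_mean, depth_cv)
  counts <- matrix(0L, n_features, n,
                   dimnames = list(ids, sprintf("%s_S%03d", study, seq_len(n))))
  for (i in seq_len(n)) {
    logits <- baseline_logits + study_bias + group[i] * log_fold +
      stats::rnorm(n_features, 0, sample_noise_sd)
    counts[, i] <- stats::rmultinom(1, depths[i], .softmax(logits))
  }
  ann <- data.frame(feature_id = ids, phylum = phyla, display_name = ids,
                    stringsAsFactors = FALSE)
  md <- sample_metadata(sample_id = colnames(counts), study = study,
                        response = ifelse(group == 1, "R", "NR"),
                        subject_id = colnames(counts))
  truth <- structure(list(effects = effects, baseline_logits = baseline_logits,
                          study_bias = stats::setNames(list(study_bias), study),
                          depths = depths),
                     class = "synthetic_truth")
  list(table = feature_table(counts, "taxon", ann), metadata = md, truth = truth)
}

#' Simulate a multi-study biomarker layout
#'
#' Produces one case-control bundle per study with a shared baseline
#' composition and independent study-specific bias, plus ground truth for the
#' cross-study consolidation rules. `consistent_positive` features carry a
#' positive planted effect in every study (so they satisfy the inclusion rule
#' and survive validation); `inconsistent` features are positive in the first
#' two studies and negative in the third, so the opposite-call exclusion rule
#' must remove them.
#'
#' @param studies Data frame with columns `name`, `n_R`, `n_NR` and
#'   optionally `phase` (`discovery` / `validation`).
#' @param n_features Number of species per study table.
#' @param consistent_positive,inconsistent Character vectors of feature ids
#'   (disjoint; `sp001`-style ids).
#' @param effect_size Magnitude of planted log-fold effects (default `log(4)`).
#' @param seed Integer seed.
#' @param ... Passed to [generate_case_control_study()].
#' @return List with `bundles` (named list of study bundles) and `truth`;
#'   `truth$consolidated_truth` is the set the consolidation rules should
#'   recover.
#' @export
generate_multi_study <- function(studies, n_features = 200,
                                 consistent_positive = character(),
                                 inconsistent = character(),
                                 effect_size = log(4), seed = 1, ...) {
  stopifnot(is.data.frame(studies), nrow(studies) >= 2)
  if (!"phase" %in% names(studies)) studies$phase <- "discovery"
  if (length(intersect(consistent_positive, inconsistent))) {
    stop("consistent_positive and inconsistent feature sets overlap")
  }
  if (length(inconsistent) && nrow(studies) < 3) {
    stop("inconsistent effects need at least 3 studies")
  }
  ids <- .feature_ids(n_features)
  unknown <- setdiff(c(consistent_positive, inconsistent), ids)
  if (length(unknown)) stop("unknown feature ids: ", paste(unknown, collapse = ", "))

  set.seed(split_seed(seed, "multi_study", "shared"))
  baseline <- stats::setNames(stats::rnorm(n_features, 0, 2), ids)
  planted <- c(consistent_positive, inconsistent)
  if (length(planted)) baseline[planted] <- pmax(baseline[planted], -1)

  bundles <- list()
  truth_effects <- list()
  for (k in seq_len(nrow(studies))) {
    name <- studies$name[k]
    lf <- c(stats::setNames(rep(effect_size, length(consistent_positive)),
                            consistent_positive),
            if (length(inconsistent)) {
              stats::setNames(rep(if (k <= 2) effect_size else -effect_size,
                                  length(inconsistent)), inconsistent)
            })
    eff <- if (length(lf)) data.frame(feature_id = names(lf), log_fold = unname(lf),
                                      stringsAsFactors = FALSE) else NULL
    bundles[[name]] <- generate_case_control_study(
      n_R = studies$n_R[k], n_NR = studies$n_NR[k], n_features = n_features,
      effects = eff, seed = split_seed(seed, "multi_study", name),
      study = name, baseline_logits = baseline, ...)
    truth_effects[[name]] <- eff
  }
  truth <- structure(list(effects = truth_effects,
                          consolidated_truth = consistent_positive,
                          inconsistent = inconsistent,
                          studies = studies),
                     class = "synthetic_truth")
  list(bundles = bundles, truth = truth)
}

#' Simulate a fecal microbiota transplantation cohort
#'
#' Donors carry donor-specific species sets; each recipient (randomly
#' assigned one donor) has a pre-FMT baseline community, and post-FMT samples
#' mix the recipient baseline with donor species that engraft with a
#' response-dependent probability. The returned truth labels every species
#' per recipient as `donor_derived`, `recipient_derived`, `common`, `new` or
#' `absent`, the profile-level analogue of read-level colonization tracking.
#'
#' @param n_donors,n_recipients Cohort sizes; recipients alternate R/NR.
#' @param timepoints Days relative to FMT; must include a baseline (<= 0).
#' @param engraftment_prob_R,engraftment_prob_NR Engraftment probability of a
#'   donor-specific species in responders / nonresponders.
#' @param response_linked Optional feature ids whose engraftment alone is
#'   response-modulated; when given, all other species engraft at the mean of
#'   the two probabilities regardless of response. Response-linked species are
#'   forced to be plantable: carried by every donor and absent from every
#'   recipient baseline.
#' @param n_features,depth_mean,depth_cv,seed,study As in
#'   [generate_case_control_study()].
#' @param donor_carriage,baseline_carriage Per-species carriage probability
#'   in donors / recipient baselines (defaults 0.45).
#' @param prob_new Probability that a species absent from both donor and
#'   baseline newly appears post-FMT (default 0.02).
#' @param mix_donor Weight of the donor community in post-FMT mixtures
#'   (default 0.4).
#' @return List with `table`, `metadata` (donors, baselines and post-FMT
#'   samples; recipients carry their donor id) and `truth` with
#'   `engraftment_truth[[recipient]]` category vectors.
#' @export
generate_fmt_cohort <- function(n_donors = 5, n_recipients = 10,
                                timepoints = c(-7, 14, 30),
                                engraftment_prob_R = 0.8,
                                engraftment_prob_NR = 0.4,
                                response_linked = NULL,
                                n_features = 120, depth_mean = 10000,
                                depth_cv = 0.3, seed = 1, study = "fmt1",
                                donor_carriage = 0.45,
                                baseline_carriage = 0.45,
                                prob_new = 0.02, mix_donor = 0.4) {
  stopifnot(n_donors > 0, n_recipients > 0,
            engraftment_prob_R >= 0, engraftment_prob_R <= 1,
            engraftment_prob_NR >= 0, engraftment_prob_NR <= 1)
  if (!any(timepoints <= 0)) stop("timepoints must include a pre-FMT baseline (<= 0)")
  post_tp <- sort(timepoints[timepoints > 0])
  base_tp <- min(timepoints)
  ids <- .feature_ids(n_features)
  if (!is.null(response_linked)) {
    unknown <- setdiff(response_linked, ids)
    if (length(unknown)) stop("unknown response_linked features: ",
                              paste(unknown, collapse = ", "))
  }
  set.seed(split_seed(seed, "fmt", study))
  phyla <- .synthetic_phyla(n_features)
  base_logits <- stats::rnorm(n_features, 0, 1.5)

  donors <- sprintf("D%02d", seq_len(n_donors))
  recipients <- sprintf("P%02d", seq_len(n_recipients))
  response <- rep(c("R", "NR"), length.out = n_recipients)
  # random donor assignment (each donor used about equally often) so that
  # donor identity is not systematically confounded with response
  donor_of <- stats::setNames(sample(rep(donors, length.out = n_recipients)),
                              recipients)

  # unnormalized community weights; zero = species not carried
  community <- function(carried) {
    w <- exp(base_logits + stats::rnorm(n_features, 0, 0.7))
    w[!carried] <- 0
    stats::setNames(w / sum(w), ids)
  }
  donor_comm <- lapply(donors, function(d) {
    community(stats::runif(n_features) < donor_carriage)
  })
  names(donor_comm) <- donors
  base_comm <- lapply(recipients, function(r) {
    community(stats::runif(n_features) < baseline_carriage)
  })
  names(base_comm) <- recipients
  if (!is.null(response_linked)) {
    # a planted response-linked engrafter must be plantable: carried by every
    # donor and absent from every recipient baseline
    rl <- ids %in% response_linked
    donor_comm <- lapply(donor_comm, function(w) {
      w[rl & w == 0] <- stats::median(w[w > 0])
      stats::setNames(w / sum(w), ids)
    })
    base_comm <- lapply(base_comm, function(w) {
      w[rl] <- 0
      stats::setNames(w / sum(w), ids)
    })
  }

  sample_rows <- list()
  counts_cols <- list()
  truth_labels <- list()
  draw <- function(p, id) {
    depth <- .draw_depths(1, depth_mean, depth_cv)
    stats::setNames(list(stats::rmultinom(1, depth, p)[, 1]), id)
  }
  for (d in donors) {
    id <- paste0(study, "_", d)
    counts_cols <- c(counts_cols, draw(donor_comm[[d]], id))
    sample_rows[[id]] <- data.frame(sample_id = id, study = study,
                                    response = NA_character_, subject_id = d,
                                    role = "donor", timepoint_days = NA_integer_,
                                    donor = NA_character_, stringsAsFactors = FALSE)
  }
  for (j in seq_along(recipients)) {
    r <- recipients[j]
    d <- donor_of[[r]]
    resp <- response[j]
    dc <- donor_comm[[d]]
    bc <- base_comm[[r]]
    p_resp <- if (resp == "R") engraftment_prob_R else engraftment_prob_NR
    p_vec <- rep(if (is.null(response_linked)) p_resp
                 else mean(c(engraftment_prob_R, engraftment_prob_NR)), n_features)
    if (!is.null(response_linked)) {
      p_vec[ids %in% response_linked] <- p_resp
    }
    engraftable <- dc > 0 & bc == 0
    engrafted <- engraftable & stats::runif(n_features) < p_vec
    neither <- dc == 0 & bc == 0
    newly <- neither & stats::runif(n_features) < prob_new

    labels <- rep("absent", n_features)
    labels[bc > 0 & dc == 0] <- "recipient_derived"
    labels[bc > 0 & dc > 0] <- "common"
    labels[engrafted] <- "donor_derived"
    labels[newly] <- "new"
    truth_labels[[r]] <- stats::setNames(labels, ids)

    id <- sprintf("%s_%s_T%+04d", study, r, as.integer(base_tp))
    counts_cols <- c(counts_cols, draw(bc, id))
    sample_rows[[id]] <- data.frame(sample_id = id, study = study,
                                    response = resp, subject_id = r,
                                    role = "recipient",
                                    timepoint_days = as.integer(base_tp),
                                    donor = d, stringsAsFactors = FALSE)

    post <- (1 - mix_donor) * bc
    post[engrafted] <- post[engrafted] + pmax(mix_donor * dc[engrafted], 0.002)
    post[newly] <- post[newly] + 0.004
    post <- post / sum(post)
    for (tp in post_tp) {
      id <- sprintf("%s_%s_T%+04d", study, r, as.integer(tp))
      counts_cols <- c(counts_cols, draw(post, id))
      sample_rows[[id]] <- data.frame(sample_id = id, study = study,
                                      response = resp, subject_id = r,
                                      role = "recipient",
                                      timepoint_days = as.integer(tp),
                                      donor = d, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- ids
  ann <- data.frame(feature_id = ids, phylum = phyla, display_name = ids,
                    stringsAsFactors = FALSE)
  md <- validate_sample_metadata(do.call(rbind, sample_rows))
  rownames(md) <- NULL
  truth <- structure(list(engraftment_truth = truth_labels,
                          donor_of = donor_of,
                          donor_communities = donor_comm,
                          baseline_communities = base_comm,
                          response = stats::setNames(response, recipients)),
                     class = "synthetic_truth")
  list(table = feature_table(counts, "taxon", ann), metadata = md, truth = truth)
}

#' Random taxon-to-gene-group link table
#'
#' Stand-in for the output of assembly-graph-based taxonomic annotation of
#' functional features: each gene group is linked to a small random set of
#' taxa.
#'
#' @param taxon_ids Character vector of taxa.
#' @param n_gene_groups Number of gene groups (`ko00001`-style ids).
#' @param max_taxa_per_group Upper bound on taxa linked per group.
#' @param seed Integer seed.
#' @return Data frame (`taxon_id`, `gene_group_id`).
#' @export
generate_link_table <- function(taxon_ids, n_gene_groups = 50,
                                max_taxa_per_group = 3, seed = 1) {
  set.seed(split_seed(seed, "links"))
  gg <- sprintf("K%05d", seq_len(n_gene_groups))
  rows <- lapply(gg, function(g) {
    k <- sample.int(max_taxa_per_group, 1)
    data.frame(taxon_id = sample(taxon_ids, k), gene_group_id = g,
               stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, rows))
}

#' Derive functional profiles from a taxon table
#'
#' Gene-group abundance is the copy-weighted sum of the abundances of the
#' taxa linked to it, emulating gene-family profiles assembled from
#' species-resolved profiles.
#'
#' @param taxon_table A taxon [feature_table()].
#' @param links Data frame (`taxon_id`, `gene_group_id`); every taxon must
#'   exist in the table.
#' @param copy_weights Optional numeric vector of positive per-link weights
#'   (recycled length 1 allowed; default 1).
#' @param gene_groups Optional full gene-group universe; groups without links
#'   get all-zero rows.
#' @return A `feature_table` with `feature_kind = "gene_group"`.
#' @export
derive_functional_profiles <- function(taxon_table, links, copy_weights = NULL,
                                       gene_groups = NULL) {
  stopifnot(inherits(taxon_table, "feature_table"))
  unknown <- setdiff(links$taxon_id, rownames(taxon_table$values))
  if (length(unknown)) stop("links reference unknown taxa: ",
                            paste(unknown, collapse = ", "))
  if (is.null(copy_weights)) copy_weights <- rep(1, nrow(links))
  if (length(copy_weights) == 1) copy_weights <- rep(copy_weights, nrow(links))
  if (any(copy_weights < 0)) stop("negative copy weight")
  gg <- if (is.null(gene_groups)) unique(links$gene_group_id) else gene_groups
  out <- matrix(0, length(gg), ncol(taxon_table$values),
                dimnames = list(gg, colnames(taxon_table$values)))
  for (i in seq_len(nrow(links))) {
    g <- links$gene_group_id[i]
    out[g, ] <- out[g, ] + copy_weights[i] * taxon_table$values[links$taxon_id[i], ]
  }
  feature_table(out, "gene_group")
}
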