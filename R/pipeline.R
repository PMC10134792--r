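#' Pipeline configuration
#'
#' Describes the datasets (by phase: `discovery`, `fmt`, `validation`), the
#' consistency rules, the statistics settings and the master seed of a full
#' run. Fixed published constants live in the defaults: top-20 taxa /
#' top-200 gene groups per dataset, validation magnitude floor 0.1,
#' denominator threshold -0.5, 10,000 permutations.
#'
#' @param datasets Data frame with columns `name`, `table`, `metadata`,
#'   `phase` and optionally `dialect`, `feature_kind`.
#' @param rules A [consistency_rules()] object.
#' @param n_permutations Permutations for PERMANOVA (>= 100).
#' @param alpha Significance level used in reports.
#' @param pseudocount Pseudocount for Aitchison distances on counts.
#' @param min_prevalence Pre-ranking prevalence filter (default 0.1).
#' @param seed Master seed; all stage seeds are split from it.
#' @param output_dir Where TSV/JSON artifacts are written.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets, rules = consistency_rules(),
                            n_permutations = 10000, alpha = 0.05,
                            pseudocount = 1, min_prevalence = 0.1,
                            seed = 1, output_dir = NULL) {
  stopifnot(is.data.frame(datasets),
            all(c("name", "table", "metadata", "phase") %in% names(datasets)))
  if (!all(datasets$phase %in% c("discovery", "fmt", "validation"))) {
    stop("dataset phase must be discovery, fmt or validation")
  }
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (!"dialect" %in% names(datasets)) datasets$dialect <- "generic_tsv"
  if (!"feature_kind" %in% names(datasets)) datasets$feature_kind <- "taxon"
  structure(list(datasets = datasets, rules = rules,
                 stats = list(n_permutations = n_permutations, alpha = alpha,
                              pseudocount = pseudocount,
                              min_prevalence = min_prevalence),
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with fields `datasets` (array of objects with
#'   `name`, `table`, `metadata`, `phase`), optional `rules`, `stats`,
#'   `seed`, `output_dir`. Relative dataset paths are resolved against the
#'   config file's directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- as.data.frame(cfg$datasets, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  ds$table <- resolve(ds$table)
  ds$metadata <- resolve(ds$metadata)
  rules <- do.call(consistency_rules, as.list(cfg$rules %||% list()))
  st <- cfg$stats %||% list()
  pipeline_config(ds, rules,
                  n_permutations = st$n_permutations %||% 10000,
                  alpha = st$alpha %||% 0.05,
                  pseudocount = st$pseudocount %||% 1,
                  min_prevalence = st$min_prevalence %||% 0.1,
                  seed = cfg$seed %||% 1,
                  output_dir = cfg$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_dataset <- function(row) {
  tab <- read_feature_table(row$table, dialect = row$dialect,
                            feature_kind = row$feature_kind)
  md <- read_sample_metadata(row$metadata)
  list(name = row$name, table = tab, metadata = md,
       feature_kind = row$feature_kind)
}

.k_for <- function(rules, feature_kind) {
  if (feature_kind == "gene_group") rules$top_k_functions else rules$top_k_taxa
}

.log_line <- function(stage, dataset, ...) {
  message(sprintf("[%s] dataset=%s %s", stage, dataset,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " ")))
}

.echo_config <- function(config, dir) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  echo <- list(datasets = config$datasets, rules = unclass(config$rules),
               stats = config$stats, seed = config$seed,
               version = as.character(utils::packageVersion("codamarker")))
  jsonlite::write_json(echo, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Rank one dataset and call top-k associations
#'
#' Convenience wrapper over the per-dataset discovery stage: prevalence
#' filter, multinomial differential ranking, top-k association calling and a
#' log-ratio group assessment of the called sets.
#'
#' @param table,metadata One dataset.
#' @param rules A [consistency_rules()].
#' @param min_prevalence Pre-ranking prevalence filter.
#' @param regularization,seed Passed to [fit_differentials()].
#' @return List with `result` (differential_result), `calls` and
#'   `log_ratio` (a [log_ratio_group_test()] result or `NULL`).
#' @export
rank_dataset <- function(table, metadata, rules = consistency_rules(),
                         min_prevalence = 0.1, regularization = 100, seed = 1) {
  tab <- filter_by_prevalence(table, min_prevalence)
  res <- fit_differentials(tab, metadata, regularization = regularization,
                           seed = seed)
  calls <- call_top_k(res, .k_for(rules, tab$feature_kind))
  num <- calls$feature_id[calls$call == "RMI"]
  den <- calls$feature_id[calls$call == "UMI"]
  lr <- NULL
  if (length(num) && length(den)) {
    lr <- log_ratio_group_test(tab, num, den, metadata)
  } else {
    warning("no two-sided calls; log-ratio assessment skipped")
  }
  list(result = res, calls = calls, log_ratio = lr)
}

#' Run the discovery phase
#'
#' Per discovery dataset: prevalence filter, differential ranking, top-k
#' calls and a log-ratio assessment; then cross-dataset consolidation of both
#' directions. Datasets whose fit does not converge are kept but flagged.
#'
#' @param config A [pipeline_config()] with at least 2 discovery datasets.
#' @param bundles Optional named list of in-memory datasets
#'   (`list(table=, metadata=)`) overriding file loading; used by the
#'   simulation-driven tests.
#' @return List with `results`, `calls` (rbind over datasets), `log_ratios`,
#'   `ledgers` (RMI and UMI [consolidate()] ledgers) and `flagged` (names of
#'   non-converged datasets).
#' @export
run_discovery <- function(config, bundles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- config$datasets[config$datasets$phase == "discovery", , drop = FALSE]
  if (nrow(rows) < 2) stop("consolidation needs at least 2 discovery datasets")
  out_dir <- config$output_dir
  .echo_config(config, out_dir)
  results <- list(); calls <- list(); lrs <- list(); flagged <- character()
  for (i in seq_len(nrow(rows))) {
    nm <- rows$name[i]
    ds <- if (!is.null(bundles)) c(list(name = nm), bundles[[nm]])
          else .load_dataset(rows[i, ])
    t0 <- Sys.time()
    ranked <- rank_dataset(ds$table, ds$metadata, config$rules,
                           config$stats$min_prevalence,
                           seed = split_seed(config$seed, "discovery", nm))
    .log_line("discovery", nm,
              n_features = length(ranked$result$feature_ids),
              n_samples = ncol(ds$table$values),
              runtime_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    if (!ranked$result$fit_info$converged) flagged <- c(flagged, nm)
    results[[nm]] <- ranked$result
    calls[[nm]] <- ranked$calls
    lrs[[nm]] <- ranked$log_ratio
    if (!is.null(out_dir)) {
      write_differentials(ranked$result,
                          file.path(out_dir, paste0("differentials_", nm, ".tsv")))
    }
  }
  all_calls <- do.call(rbind, calls)
  rownames(all_calls) <- NULL
  ledgers <- list(RMI = consolidate(all_calls, config$rules, "RMI"),
                  UMI = consolidate(all_calls, config$rules, "UMI"))
  if (length(flagged)) {
    warning("non-converged datasets flagged in consolidation: ",
            paste(flagged, collapse = ", "))
  }
  if (!is.null(out_dir)) {
    utils::write.table(all_calls, file.path(out_dir, "calls_discovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ledger(ledgers$RMI, file.path(out_dir, "ledger_discovery_RMI.tsv"))
    write_ledger(ledgers$UMI, file.path(out_dir, "ledger_discovery_UMI.tsv"))
  }
  list(results = results, calls = all_calls, log_ratios = lrs,
       ledgers = ledgers, flagged = flagged)
}

#' Run the FMT phase
#'
#' Per FMT dataset: classify species origin per post-FMT sample, assemble the
#' donor-derived table, decompose its variance by donor and response, rank
#' donor-derived profiles against response and call top-k associations. The
#' returned calls can be merged with discovery calls before consolidation.
#'
#' @param config A [pipeline_config()] with at least one `fmt` dataset.
#' @param bundles Optional in-memory datasets (see [run_discovery()]).
#' @return List with `calls`, `results`, `variance` (per dataset) and
#'   `profiles`.
#' @export
run_fmt <- function(config, bundles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- config$datasets[config$datasets$phase == "fmt", , drop = FALSE]
  if (nrow(rows) < 1) stop("no FMT datasets configured")
  out_dir <- config$output_dir
  results <- list(); calls <- list(); variance <- list(); profiles <- list()
  for (i in seq_len(nrow(rows))) {
    nm <- rows$name[i]
    ds <- if (!is.null(bundles)) c(list(name = nm), bundles[[nm]])
          else .load_dataset(rows[i, ])
    prof <- cohort_engraftment_profiles(ds$table, ds$metadata)
    dd <- donor_derived_table(prof)
    if (all(dd$values == 0)) {
      warning("no donor-derived species detected in ", nm,
              "; empty call set for this dataset")
      profiles[[nm]] <- prof
      next
    }
    md_dd <- ds$metadata[match(colnames(dd$values), ds$metadata$sample_id), ]
    vd <- variance_decomposition(dd, md_dd,
                                 n_permutations = config$stats$n_permutations,
                                 seed = split_seed(config$seed, "fmt_permanova", nm),
                                 pseudocount = config$stats$pseudocount)
    dd_f <- filter_by_prevalence(dd, config$stats$min_prevalence)
    res <- fit_differentials(dd_f, ds$metadata,
                             seed = split_seed(config$seed, "fmt_rank", nm))
    res$study <- nm
    k <- .k_for(config$rules, ds$table$feature_kind)
    cl <- call_top_k(res, k)
    cl$study <- nm
    .log_line("fmt", nm, n_recipients = length(unique(md_dd$subject_id)),
              n_post_samples = ncol(dd$values))
    results[[nm]] <- res; calls[[nm]] <- cl
    variance[[nm]] <- vd; profiles[[nm]] <- prof
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_engraftment(prof, ds$metadata,
                        file.path(out_dir, paste0("engraftment_", nm, ".tsv")))
      utils::write.table(vd, file.path(out_dir, paste0("variance_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_differentials(res,
                          file.path(out_dir, paste0("differentials_dd_", nm, ".tsv")))
    }
  }
  all_calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(feature_id = character(), study = character(),
               call = character(), stringsAsFactors = FALSE)
  rownames(all_calls) <- NULL
  list(calls = all_calls, results = results, variance = variance,
       profiles = profiles)
}

#' Run the validation phase
#'
#' Fits differentials in each validation dataset, applies the validation
#' rules to a consolidated ledger, selects log-ratio denominators
#' (differential < -0.5; falling back to the bottom-k calls when the
#' threshold selects nothing) and runs the log-ratio group assessment of the
#' validated set in every validation dataset. An empty validated set is a
#' legitimate outcome, not an error.
#'
#' @param config A [pipeline_config()] with at least one validation dataset.
#' @param ledger A consolidated [biomarker_ledger][consolidate()].
#' @param bundles Optional in-memory datasets (see [run_discovery()]).
#' @return List with `ledger` (validated), `results`, `denominators` and
#'   `log_ratios` per validation dataset.
#' @export
run_validation <- function(config, ledger, bundles = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(ledger, "biomarker_ledger"))
  rows <- config$datasets[config$datasets$phase == "validation", , drop = FALSE]
  if (nrow(rows) < 1) stop("no validation datasets configured")
  out_dir <- config$output_dir
  results <- list(); tables <- list(); mds <- list()
  for (i in seq_len(nrow(rows))) {
    nm <- rows$name[i]
    ds <- if (!is.null(bundles)) c(list(name = nm), bundles[[nm]])
          else .load_dataset(rows[i, ])
    tab <- filter_by_prevalence(ds$table, config$stats$min_prevalence)
    res <- fit_differentials(tab, ds$metadata,
                             seed = split_seed(config$seed, "validation", nm))
    res$study <- nm
    .log_line("validation", nm, n_features = length(res$feature_ids),
              n_samples = ncol(tab$values))
    results[[nm]] <- res
    tables[[nm]] <- tab
    mds[[nm]] <- ds$metadata
  }
  ledger <- validate_biomarkers(ledger, results, config$rules)
  denominators <- list(); lrs <- list()
  validated <- ledger$validated$feature_id
  for (nm in names(results)) {
    den <- tryCatch(select_denominator(results[[nm]], config$rules),
                    error = function(e) {
                      warning("denominator threshold empty in ", nm,
                              "; falling back to bottom-k calls")
                      cl <- call_top_k(results[[nm]], .k_for(config$rules, "taxon"))
                      cl$feature_id[cl$call == "UMI"]
                    })
    denominators[[nm]] <- den
    if (length(validated) && length(setdiff(den, validated))) {
      lrs[[nm]] <- log_ratio_group_test(tables[[nm]], validated,
                                        setdiff(den, validated), mds[[nm]])
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ledger(ledger, file.path(out_dir, "ledger_validated.tsv"))
    lr_rows <- lapply(names(lrs), function(nm) {
      data.frame(study = nm, test = lrs[[nm]]$test,
                 n_dropped = lrs[[nm]]$n_dropped,
                 p_value = lrs[[nm]]$group_p_value, stringsAsFactors = FALSE)
    })
    if (length(lr_rows)) {
      utils::write.table(do.call(rbind, lr_rows),
                         file.path(out_dir, "log_ratio_validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(ledger = ledger, results = results, denominators = denominators,
       log_ratios = lrs)
}

#' Run the full pipeline
#'
#' Discovery ranking and consolidation, optional FMT donor-derived analysis
#' (whose calls are merged with the discovery calls before consolidation, so
#' group-comparison and FMT evidence enter the same ledger), and optional
#' validation. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param bundles Optional in-memory datasets (named by dataset).
#' @return List with `discovery`, `fmt` (or `NULL`), `ledgers` (post-merge),
#'   `validation` (or `NULL`).
#' @export
run_pipeline <- function(config, bundles = NULL) {
  disc <- run_discovery(config, bundles)
  fmt <- NULL
  merged <- disc$calls
  if (any(config$datasets$phase == "fmt")) {
    fmt <- run_fmt(config, bundles)
    merged <- rbind(merged, fmt$calls)
  }
  ledgers <- list(RMI = consolidate(merged, config$rules, "RMI"),
                  UMI = consolidate(merged, config$rules, "UMI"))
  validation <- NULL
  if (any(config$datasets$phase == "validation")) {
    validation <- run_validation(config, ledgers$RMI, bundles)
    ledgers$RMI <- validation$ledger
  }
  if (!is.null(config$output_dir)) {
    write_ledger(ledgers$RMI, file.path(config$output_dir, "ledger_final_RMI.tsv"))
    write_ledger(ledgers$UMI, file.path(config$output_dir, "ledger_final_UMI.tsv"))
  }
  list(discovery = disc, fmt = fmt, ledgers = ledgers, validation = validation)
}
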