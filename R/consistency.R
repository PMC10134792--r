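#' Cross-study consistency rules
#'
#' Bundles the constants of the published rule system: a species (or gene
#' group) becomes a consistent biomarker when called in the same direction in
#' more than one dataset and never in the opposite direction in any dataset;
#' at validation, candidates must keep a same-sign differential of magnitude
#' at least 0.1 in every validation dataset; and log-ratio denominators are
#' the features with differentials below -0.5.
#'
#' @param min_supporting_datasets Minimum supporting datasets (default 2).
#' @param exclusion_on_any_opposite Exclude on any opposite-direction call
#'   (default `TRUE`).
#' @param validation_min_abs_differential Minimum |differential| in every
#'   validation dataset (default 0.1).
#' @param denominator_max_differential Strict upper bound for denominator
#'   selection (default -0.5).
#' @param top_k_taxa,top_k_functions Top-k list sizes for taxa (20) and gene
#'   groups (200).
#' @return A list of class `consistency_rules`.
#' @export
consistency_rules <- function(min_supporting_datasets = 2,
                              exclusion_on_any_opposite = TRUE,
                              validation_min_abs_differential = 0.1,
                              denominator_max_differential = -0.5,
                              top_k_taxa = 20,
                              top_k_functions = 200) {
  if (min_supporting_datasets < 2) stop("min_supporting_datasets must be >= 2")
  stopifnot(is.finite(validation_min_abs_differential),
            is.finite(denominator_max_differential))
  structure(list(min_supporting_datasets = min_supporting_datasets,
                 exclusion_on_any_opposite = exclusion_on_any_opposite,
                 validation_min_abs_differential = validation_min_abs_differential,
                 denominator_max_differential = denominator_max_differential,
                 top_k_taxa = top_k_taxa,
                 top_k_functions = top_k_functions),
            class = "consistency_rules")
}

#' Consolidate per-dataset association calls
#'
#' Applies the two-rule scheme to calls from several datasets: (i) a feature
#' called in the target direction in at least `min_supporting_datasets`
#' datasets enters the consolidated list; (ii) a feature called in the
#' opposite direction in even one dataset is excluded regardless of how many
#' datasets support it. Exclusions are recorded with a reason
#' (`opposite_call` or `insufficient_support`). The operation is pure set
#' logic: deterministic and independent of input row order.
#'
#' @param calls Data frame (`feature_id`, `study`, `call`) as produced by
#'   [call_top_k()], concatenated over datasets (at least 2 studies).
#' @param rules A [consistency_rules()] object.
#' @param direction `"RMI"` or `"UMI"` - which direction to consolidate.
#' @return An object of class `biomarker_ledger` with `calls`, `direction`,
#'   `consolidated` (data frame `feature_id`, `n_support`,
#'   `supporting_studies`), `removed` (data frame `feature_id`, `reason`) and
#'   an empty `validated` slot.
#' @export
consolidate <- function(calls, rules = consistency_rules(),
                        direction = c("RMI", "UMI")) {
  direction <- match.arg(direction)
  stopifnot(all(c("feature_id", "study", "call") %in% names(calls)))
  calls <- unique(calls[, c("feature_id", "study", "call")])
  if (length(unique(calls$study)) < 2) stop("calls must cover at least 2 studies")
  opposite <- if (direction == "RMI") "UMI" else "RMI"
  candidates <- sort(unique(calls$feature_id[calls$call == direction]))
  cons <- list(); rem <- list()
  for (f in candidates) {
    sup <- sort(unique(calls$study[calls$feature_id == f & calls$call == direction]))
    opp <- unique(calls$study[calls$feature_id == f & calls$call == opposite])
    if (rules$exclusion_on_any_opposite && length(opp) > 0) {
      rem[[f]] <- "opposite_call"
    } else if (length(sup) < rules$min_supporting_datasets) {
      rem[[f]] <- "insufficient_support"
    } else {
      cons[[f]] <- data.frame(feature_id = f, n_support = length(sup),
                              supporting_studies = paste(sup, collapse = ","),
                              stringsAsFactors = FALSE)
    }
  }
  consolidated <- if (length(cons)) do.call(rbind, cons) else
    data.frame(feature_id = character(), n_support = integer(),
               supporting_studies = character(), stringsAsFactors = FALSE)
  rownames(consolidated) <- NULL
  removed <- data.frame(feature_id = names(rem),
                        reason = unlist(rem, use.names = FALSE),
                        stringsAsFactors = FALSE)
  structure(list(calls = calls, direction = direction, rules = rules,
                 consolidated = consolidated, removed = removed,
                 validated = NULL),
            class = "biomarker_ledger")
}

#' @export
print.biomarker_ledger <- function(x, ...) {
  cat(sprintf("<biomarker_ledger> %s: %d consolidated, %d removed%s\n",
              x$direction, nrow(x$consolidated), nrow(x$removed),
              if (!is.null(x$validated)) sprintf(", %d validated", nrow(x$validated)) else ""))
  invisible(x)
}

#' Validate consolidated biomarkers on held-out datasets
#'
#' A consolidated feature survives validation only if its differential keeps
#' the biomarker's sign in *every* validation dataset and its magnitude is at
#' least `validation_min_abs_differential` in every validation dataset.
#' Features failing the sign test are removed as `contradiction_in_validation`;
#' features passing the sign test but falling below the magnitude floor are
#' removed as `below_magnitude`. A feature absent from a validation dataset
#' (e.g. filtered by prevalence) is conservatively treated as a
#' contradiction, with a warning.
#'
#' @param ledger A [consolidate()] ledger.
#' @param validation_results List of [fit_differentials()] results from
#'   datasets disjoint from the discovery studies.
#' @param rules A [consistency_rules()] object.
#' @return The ledger with `validated` (data frame like `consolidated`) and
#'   extra rows in `removed`.
#' @export
validate_biomarkers <- function(ledger, validation_results,
                                rules = consistency_rules()) {
  stopifnot(inherits(ledger, "biomarker_ledger"), length(validation_results) >= 1)
  val_studies <- vapply(validation_results, `[[`, character(1), "study")
  disc_studies <- unique(ledger$calls$study)
  overlap <- intersect(val_studies, disc_studies)
  if (length(overlap)) {
    stop("validation studies overlap discovery studies: ",
         paste(overlap, collapse = ", "))
  }
  sign_ok <- if (ledger$direction == "RMI") function(d) d > 0 else function(d) d < 0
  keep <- list(); rem <- list()
  for (f in ledger$consolidated$feature_id) {
    d <- vapply(validation_results, function(r) {
      if (f %in% names(r$differentials)) unname(r$differentials[f]) else NA_real_
    }, numeric(1))
    if (anyNA(d)) {
      warning("feature '", f, "' absent from validation dataset(s) ",
              paste(val_studies[is.na(d)], collapse = ", "),
              "; treated as contradiction")
      rem[[f]] <- "contradiction_in_validation"
    } else if (!all(sign_ok(d))) {
      rem[[f]] <- "contradiction_in_validation"
    } else if (!all(abs(d) >= rules$validation_min_abs_differential)) {
      rem[[f]] <- "below_magnitude"
    } else {
      keep[[f]] <- TRUE
    }
  }
  ledger$validated <- ledger$consolidated[
    ledger$consolidated$feature_id %in% names(keep), , drop = FALSE]
  rownames(ledger$validated) <- NULL
  if (length(rem)) {
    ledger$removed <- rbind(ledger$removed,
                            data.frame(feature_id = names(rem),
                                       reason = unlist(rem, use.names = FALSE),
                                       stringsAsFactors = FALSE))
  }
  ledger
}

#' Select log-ratio denominators from a differential ranking
#'
#' When no validated biomarkers of unresponsiveness are available, the
#' denominator of the log-ratio assessment is the set of features with
#' differential strictly below `denominator_max_differential` (default -0.5).
#'
#' @param result A [fit_differentials()] result.
#' @param rules A [consistency_rules()] object.
#' @return Character vector of feature ids.
#' @export
select_denominator <- function(result, rules = consistency_rules()) {
  stopifnot(inherits(result, "differential_result"))
  d <- result$differentials
  sel <- names(d)[d < rules$denominator_max_differential]
  if (!length(sel)) {
    stop("no feature has differential below ",
         rules$denominator_max_differential,
         "; consider falling back to the bottom-k UMI calls")
  }
  sort(sel)
}

#' Export a biomarker ledger as TSV
#'
#' One row per feature that was consolidated, validated or removed, in the
#' shape of a published consistent-biomarker table: feature, phylum,
#' direction, supporting studies, status and removal reason.
#'
#' @param ledger A [consolidate()] / [validate_biomarkers()] ledger.
#' @param path Output path.
#' @param annotations Optional annotation data frame (`feature_id`, `phylum`).
#' @return The exported data frame, invisibly.
#' @export
write_ledger <- function(ledger, path, annotations = NULL) {
  cons <- ledger$consolidated
  status <- rep("consolidated", nrow(cons))
  if (!is.null(ledger$validated)) {
    status[cons$feature_id %in% ledger$validated$feature_id] <- "validated"
    status[cons$feature_id %in%
             ledger$removed$feature_id] <- "removed_in_validation"
  }
  rows <- data.frame(feature_id = cons$feature_id,
                     direction = ledger$direction,
                     supporting_studies = cons$supporting_studies,
                     status = status,
                     removal_reason = NA_character_,
                     stringsAsFactors = FALSE)
  if (nrow(ledger$removed)) {
    rm_rows <- data.frame(feature_id = ledger$removed$feature_id,
                          direction = ledger$direction,
                          supporting_studies = NA_character_,
                          status = "removed",
                          removal_reason = ledger$removed$reason,
                          stringsAsFactors = FALSE)
    idx <- match(rm_rows$feature_id, rows$feature_id)
    hit <- !is.na(idx)
    rows$removal_reason[idx[hit]] <- rm_rows$removal_reason[hit]
    rows$status[idx[hit]] <- "removed_in_validation"
    rows <- rbind(rows, rm_rows[!hit, ])
  }
  rows$phylum <- NA_character_
  if (!is.null(annotations)) {
    rows$phylum <- annotations$phylum[match(rows$feature_id, annotations$feature_id)]
  }
  rows <- rows[, c("feature_id", "phylum", "direction", "supporting_studies",
                   "status", "removal_reason")]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
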