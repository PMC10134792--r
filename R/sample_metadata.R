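#' Build and validate per-sample metadata
#'
#' Sample metadata links each metagenome to its study, treatment-response
#' label, subject, and (for fecal microbiota transplantation cohorts) the
#' donor/recipient role and timepoint. Responders are labelled `R`,
#' nonresponders `NR`; donors carry `NA` because response is a property of
#' the treated patient.
#'
#' @param sample_id,study,subject_id Character vectors.
#' @param response Character vector with entries `"R"`, `"NR"` or `NA`.
#' @param role One of `"patient"`, `"donor"`, `"recipient"` per sample.
#' @param timepoint_days Integer days relative to FMT (values <= 0 are
#'   pre-FMT baselines); `NA` for non-FMT samples.
#' @param donor Donor subject assigned to a recipient (`NA` otherwise).
#' @return A data frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, study, response,
                            subject_id = sample_id,
                            role = "patient",
                            timepoint_days = NA_integer_,
                            donor = NA_character_) {
  md <- data.frame(sample_id = as.character(sample_id),
                   study = as.character(study),
                   response = as.character(response),
                   subject_id = as.character(subject_id),
                   role = as.character(role),
                   timepoint_days = as.integer(timepoint_days),
                   donor = as.character(donor),
                   stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

#' @rdname sample_metadata
#' @param md A data frame with at least `sample_id`, `study`, `response`.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "study", "response")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (!"subject_id" %in% names(md)) md$subject_id <- md$sample_id
  if (!"role" %in% names(md)) md$role <- "patient"
  if (!"timepoint_days" %in% names(md)) md$timepoint_days <- NA_integer_
  if (!"donor" %in% names(md)) md$donor <- NA_character_
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata")
  }
  bad_resp <- !(md$response %in% c("R", "NR") | is.na(md$response))
  if (any(bad_resp)) {
    stop("invalid response labels: ", paste(unique(md$response[bad_resp]), collapse = ", "))
  }
  bad_role <- !md$role %in% c("patient", "donor", "recipient")
  if (any(bad_role)) {
    stop("invalid roles: ", paste(unique(md$role[bad_role]), collapse = ", "))
  }
  if (any(md$role == "donor" & !is.na(md$response))) {
    stop("donor samples must have response = NA")
  }
  # every recipient needs at least one pre-FMT baseline (timepoint <= 0)
  rec <- md[md$role == "recipient", , drop = FALSE]
  if (nrow(rec)) {
    by_subj <- split(rec$timepoint_days, rec$subject_id)
    no_base <- names(by_subj)[!vapply(by_subj, function(t) any(!is.na(t) & t <= 0), logical(1))]
    if (length(no_base)) {
      stop("recipients without a pre-FMT baseline sample: ",
           paste(no_base, collapse = ", "))
    }
  }
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `study`, `response`, and
#'   optionally `subject_id`, `role`, `timepoint_days`, `donor`. Empty
#'   strings and the literal `NA` are read as missing.
#' @return A validated `sample_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_sample_metadata(md)
}

#' Write sample metadata to TSV
#'
#' @param md A `sample_metadata` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
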