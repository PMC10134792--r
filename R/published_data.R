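#' Published per-species study support for melanoma immunotherapy response
#'
#' The cross-study support table printed by the source meta-analysis: for
#' each consistent species biomarker of immunotherapy responsiveness, the
#' published melanoma cohorts in which it was a top-20 positive differential
#' call, with its phylum and the percentage of samples with nonzero relative
#' abundance. (One cohort name appears in the original once as "Matson 2019";
#' it is normalised to the 2018 dataset here.)
#'
#' @param as_calls If `TRUE`, expand to a per-(species, study) call table
#'   with `call = "RMI"`, ready for [consolidate()].
#' @return A data frame; either the support table (`species`, `phylum`,
#'   `prevalence_pct`, `supporting_studies`) or the expanded call table
#'   (`feature_id`, `study`, `call`).
#' @export
published_support_calls <- function(as_calls = FALSE) {
  path <- system.file("extdata", "rmi_support_calls.tsv", package = "codamarker")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!as_calls) return(df)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    studies <- strsplit(df$supporting_studies[i], ",", fixed = TRUE)[[1]]
    data.frame(feature_id = df$species[i], study = studies, call = "RMI",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published cohort overview
#'
#' Sample arithmetic of the seven melanoma stool-metagenome cohorts used in
#' the source meta-analysis: per-study individuals, metagenome counts and
#' responder/nonresponder splits, by analysis phase (three group-comparison
#' discovery cohorts, two FMT cohorts, two validation cohorts).
#'
#' @return Data frame (`study`, `phase`, `individuals`, `samples`,
#'   `responders`, `nonresponders`).
#' @export
published_study_overview <- function() {
  path <- system.file("extdata", "study_overview.tsv", package = "codamarker")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
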