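#' Taxon-to-gene-group link incidence
#'
#' A bipartite mapping between microbial taxa and functional gene groups
#' (e.g. KEGG orthology groups), typically derived from assembly-graph
#' context of the gene groups. Duplicate pairs are collapsed; links are
#' unweighted presence.
#'
#' @param pairs Data frame with columns `taxon_id`, `gene_group_id`.
#' @param taxon_phylum Optional named character vector mapping taxon to
#'   phylum (needed by [phylum_contrast()] and [export_link_network()]).
#' @return An object of class `link_incidence`.
#' @export
link_incidence <- function(pairs, taxon_phylum = NULL) {
  stopifnot(all(c("taxon_id", "gene_group_id") %in% names(pairs)))
  pairs <- unique(pairs[, c("taxon_id", "gene_group_id")])
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, taxon_phylum = taxon_phylum),
            class = "link_incidence")
}

#' Read a link table from TSV
#'
#' @param path TSV with columns `taxon_id`, `gene_group_id` and optionally
#'   `phylum`.
#' @return A [link_incidence()].
#' @export
read_link_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tp <- NULL
  if ("phylum" %in% names(df)) {
    u <- unique(df[, c("taxon_id", "phylum")])
    tp <- stats::setNames(u$phylum, u$taxon_id)
  }
  link_incidence(df, tp)
}

.linked_sets <- function(links) {
  split(links$pairs$gene_group_id, links$pairs$taxon_id)
}

#' Rank species by biomarker gene-group content
#'
#' Counts, per taxon, how many of the given biomarker gene groups are linked
#' to it, and orders taxa by that count (descending, ties broken by id). The
#' per-taxon coverage is the count divided by the biomarker set size.
#'
#' @param links A [link_incidence()].
#' @param biomarkers Non-empty character vector of gene-group ids.
#' @return An object of class `species_ranking` with `counts` (data frame
#'   `taxon_id`, `n_biomarkers`, `coverage`) ordered as ranked, and `order`.
#' @export
rank_species_by_biomarkers <- function(links, biomarkers) {
  stopifnot(inherits(links, "link_incidence"))
  if (!length(biomarkers)) stop("biomarker set must be non-empty")
  sets <- .linked_sets(links)
  counts <- vapply(sets, function(g) length(intersect(g, biomarkers)), integer(1))
  ord <- order(-counts, names(counts))
  df <- data.frame(taxon_id = names(counts)[ord],
                   n_biomarkers = unname(counts[ord]),
                   coverage = unname(counts[ord]) / length(biomarkers),
                   stringsAsFactors = FALSE)
  structure(list(counts = df, order = df$taxon_id,
                 n_biomarkers_total = length(biomarkers)),
            class = "species_ranking")
}

#' @export
print.species_ranking <- function(x, ...) {
  cat(sprintf("<species_ranking> %d taxa against %d biomarkers; top: %s (%d)\n",
              nrow(x$counts), x$n_biomarkers_total,
              x$counts$taxon_id[1], x$counts$n_biomarkers[1]))
  invisible(x)
}

#' Biomarker coverage of a taxon combination
#'
#' Fraction of the biomarker gene groups linked to at least one taxon of the
#' combination: `|union of linked sets intersected with biomarkers| /
#' |biomarkers|`. Monotone under adding taxa.
#'
#' @param links A [link_incidence()].
#' @param taxa Non-empty character vector of taxon ids.
#' @param biomarkers Non-empty character vector of gene-group ids.
#' @return Proportion in \[0, 1\].
#' @export
coverage_of_combination <- function(links, taxa, biomarkers) {
  stopifnot(inherits(links, "link_incidence"))
  if (!length(biomarkers)) stop("biomarker set must be non-empty")
  if (!length(taxa)) stop("taxon combination must be non-empty")
  p <- links$pairs
  covered <- unique(p$gene_group_id[p$taxon_id %in% taxa])
  length(intersect(covered, biomarkers)) / length(biomarkers)
}

#' Phylum-level contrast of biomarker content
#'
#' Compares the per-species biomarker counts between phyla with all pairwise
#' two-sided Wilcoxon rank-sum tests, Benjamini-Hochberg adjusted across
#' pairs. Phyla with fewer than 2 linked taxa are excluded with a warning.
#'
#' @param links A [link_incidence()] with `taxon_phylum` set.
#' @param biomarkers Non-empty character vector of gene-group ids.
#' @return List with `per_phylum` (named list of per-species count vectors)
#'   and `tests` (data frame `phylum_a`, `phylum_b`, `n_a`, `n_b`,
#'   `p_value`, `p_adjusted`).
#' @export
phylum_contrast <- function(links, biomarkers) {
  stopifnot(inherits(links, "link_incidence"))
  if (is.null(links$taxon_phylum)) stop("links carry no phylum annotation")
  rk <- rank_species_by_biomarkers(links, biomarkers)
  counts <- stats::setNames(rk$counts$n_biomarkers, rk$counts$taxon_id)
  phyla <- links$taxon_phylum[names(counts)]
  if (anyNA(phyla)) stop("taxa without phylum annotation: ",
                         paste(names(counts)[is.na(phyla)], collapse = ", "))
  groups <- split(unname(counts), phyla)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small)) {
    warning("phyla with < 2 taxa excluded: ", paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) < 2) stop("need at least 2 phyla with at least 2 taxa each")
  nm <- names(groups)
  combos <- utils::combn(nm, 2)
  tests <- data.frame(phylum_a = combos[1, ], phylum_b = combos[2, ],
                      n_a = vapply(combos[1, ], function(p) length(groups[[p]]), integer(1)),
                      n_b = vapply(combos[2, ], function(p) length(groups[[p]]), integer(1)),
                      p_value = apply(combos, 2, function(pr) {
                        wilcoxon_rank_sum(groups[[pr[1]]], groups[[pr[2]]])
                      }),
                      stringsAsFactors = FALSE)
  tests$p_adjusted <- benjamini_hochberg(tests$p_value)
  rownames(tests) <- NULL
  list(per_phylum = groups, tests = tests)
}

#' Export a phylum-to-gene-group network edge list
#'
#' Aggregates taxa by phylum and emits one edge per (phylum, biomarker gene
#' group) pair, weighted by the number of taxon links behind it. The total
#' edge weight equals the number of biomarker links.
#'
#' @param links A [link_incidence()] with `taxon_phylum` set.
#' @param biomarkers Character vector of gene-group ids (possibly empty).
#' @param path Optional TSV output path.
#' @return Data frame (`phylum`, `gene_group_id`, `weight`).
#' @export
export_link_network <- function(links, biomarkers, path = NULL) {
  stopifnot(inherits(links, "link_incidence"))
  p <- links$pairs[links$pairs$gene_group_id %in% biomarkers, , drop = FALSE]
  if (nrow(p) == 0) {
    edges <- data.frame(phylum = character(), gene_group_id = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  } else {
    if (is.null(links$taxon_phylum)) stop("links carry no phylum annotation")
    p$phylum <- links$taxon_phylum[p$taxon_id]
    agg <- stats::aggregate(list(weight = rep(1L, nrow(p))),
                            by = list(phylum = p$phylum,
                                      gene_group_id = p$gene_group_id),
                            FUN = sum)
    edges <- agg[order(agg$phylum, agg$gene_group_id), ]
    rownames(edges) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  edges
}
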