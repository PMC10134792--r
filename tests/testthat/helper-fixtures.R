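# Small in-code fixtures shared across test files.

# a named feature table from a plain matrix spec
tiny_table <- function(values, feature_ids = NULL, sample_ids = NULL,
                       feature_kind = "taxon", annotations = NULL) {
  m <- as.matrix(values)
  rownames(m) <- feature_ids %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("s%02d", seq_len(ncol(m)))
  feature_table(m, feature_kind, annotations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a MetaPhlAn-style merged table with known species and genus rows
write_metaphlan_fixture <- function(path) {
  lines <- c(
    "#mpa_v30_CHOCOPhlAn_201901",
    paste("clade_name", "sampleA", "sampleB", sep = "\t"),
    paste("k__Bacteria", "100", "100", sep = "\t"),
    paste("k__Bacteria|p__Firmicutes", "60", "50", sep = "\t"),
    paste("k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Ruminococcaceae|g__Faecalibacterium",
          "30", "20", sep = "\t"),
    paste("k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Ruminococcaceae|g__Faecalibacterium|s__Faecalibacterium_prausnitzii",
          "30", "20", sep = "\t"),
    paste("k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides",
          "25", "35", sep = "\t"),
    paste("k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides|s__Bacteroides_ovatus",
          "15", "20", sep = "\t"),
    paste("k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides|s__Bacteroides_vulgatus",
          "10", "15", sep = "\t"))
  writeLines(lines, path)
  path
}

# two-group metadata for a table
two_group_metadata <- function(table, n_R, study = "toy") {
  ids <- colnames(table$values)
  sample_metadata(ids, study,
                  c(rep("R", n_R), rep("NR", length(ids) - n_R)))
}

# brute-force two-sided Wilcoxon rank-sum p by enumerating group assignments
brute_force_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  mu <- n1 * (length(pooled) + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force PERMANOVA: exact p over all distinct label assignments
brute_force_permanova_p <- function(D, labels) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)
  g <- length(unique(labels))
  fstat <- function(lab) {
    w <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      w <- w + sum(D2[idx, idx]) / (2 * length(idx))
    }
    if (w <= 0) return(Inf)
    ((ss_total - w) / (g - 1)) / (w / (n - g))
  }
  f_obs <- fstat(labels)
  sizes <- table(labels)
  stopifnot(length(sizes) == 2)  # enumeration helper for two groups
  n1 <- sizes[[1]]
  lv <- names(sizes)
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep(lv[2], n); lab[idx] <- lv[1]
    fstat(lab)
  })
  mean(f_all >= f_obs - 1e-12)
}

# independent clr/Aitchison implementation used as oracle
oracle_aitchison <- function(x, y) {
  gx <- exp(mean(log(x))); gy <- exp(mean(log(y)))
  sqrt(sum((log(x / gx) - log(y / gy))^2))
}
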