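## Stage-specific expression profiles, k-means clustering, and paralog-pair
## expression-divergence calls.

#' Per-gene z-score profiles across developmental stages
#'
#' Optionally log-transforms (`log2(x + pseudocount)`) and then standardizes
#' each gene across stages to mean 0, sd 1. Genes with zero variance across
#' stages get an all-zero profile and are flagged constant. Genes whose
#' dynamic range across stages is below `min_range` (log2 units, i.e. less
#' than a 2-fold change at the default) also get a flat all-zero profile
#' and a `low_signal` flag: standardizing a no-signal profile only amplifies
#' measurement noise to unit variance, which would scatter such genes
#' across pattern clusters.
#'
#' @param mat Numeric matrix, genes x stages, non-negative, with row and
#'   column names.
#' @param log_transform Apply `log2(x + pseudocount)` first (default TRUE).
#' @param pseudocount Added before the log (default 1).
#' @param min_range Minimum max-min range (in log2 units after transform)
#'   for a gene to receive a standardized profile (default 1).
#' @return Object of class `stage_profiles`: list with `z` (matrix),
#'   `peak_stage` (named character), `specificity` (max z per gene),
#'   `constant` (logical), `low_signal` (logical), `flat` (either flag),
#'   `stages`.
#' @export
zscore_profiles <- function(mat, log_transform = TRUE, pseudocount = 1,
                            min_range = 1) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 stages")
  if (any(mat < 0)) stop("expression values must be non-negative")
  if (is.null(colnames(mat))) stop("stage (column) names required")
  x <- if (log_transform) log2(mat + pseudocount) else mat
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  rng <- apply(x, 1, function(v) max(v) - min(v))
  constant <- sdv == 0
  low_signal <- !constant & rng < min_range
  flat <- constant | low_signal
  z <- (x - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  peak <- colnames(z)[max.col(z, ties.method = "first")]
  structure(list(z = z,
                 peak_stage = stats::setNames(peak, rownames(z)),
                 specificity = stats::setNames(apply(z, 1, max), rownames(z)),
                 constant = stats::setNames(constant, rownames(z)),
                 low_signal = stats::setNames(low_signal, rownames(z)),
                 flat = stats::setNames(flat, rownames(z)),
                 stages = colnames(z)),
            class = "stage_profiles")
}

#' @export
print.stage_profiles <- function(x, ...) {
  cat(sprintf("<stage_profiles> %d genes x %d stages (%d constant)\n",
              nrow(x$z), length(x$stages), sum(x$constant)))
  invisible(x)
}

#' K-means clustering of stage z-profiles
#'
#' Euclidean k-means on the z-score matrix, best of `n_init` restarts;
#' deterministic for a fixed `seed`.
#'
#' @param profiles A [zscore_profiles()] result.
#' @param k Number of clusters (default 8).
#' @param seed RNG seed.
#' @param n_init Number of random restarts (default 20).
#' @return Named integer vector gene -> cluster (1..k).
#' @export
cluster_stage_patterns <- function(profiles, k = 8L, seed = 1L, n_init = 20L) {
  z <- profiles$z
  if (k > nrow(z)) stop("k exceeds the number of genes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  stats::setNames(km$cluster, rownames(z))
}

#' Stage specificity of a gene's profile
#'
#' A gene is stage-specific when exactly one stage's z-score reaches
#' `z_threshold`; constant genes are never specific.
#'
#' @param profiles A [zscore_profiles()] result.
#' @param z_threshold Z threshold (default 1.5).
#' @return data.frame with `gene`, `is_stage_specific`, `peak_stage`.
#' @export
stage_specificity <- function(profiles, z_threshold = 1.5) {
  hi <- rowSums(profiles$z >= z_threshold)
  spec <- hi == 1 & !profiles$flat
  data.frame(gene = rownames(profiles$z),
             is_stage_specific = unname(spec),
             peak_stage = ifelse(spec, unname(profiles$peak_stage), NA),
             stringsAsFactors = FALSE)
}

#' Expression-divergence call for a paralog pair
#'
#' A pair is divergent when the Pearson correlation of the two z-profiles
#' falls below `r_threshold`, or when both genes are stage-specific with
#' different peak stages. If one profile is constant the correlation is
#' undefined and the call rests on the peak criterion alone (flagged).
#'
#' @param profiles A [zscore_profiles()] result containing both genes.
#' @param geneA,geneB Gene ids.
#' @param r_threshold Correlation threshold (default 0.5).
#' @param z_threshold Stage-specificity threshold passed through.
#' @return List with `divergent`, `r`, `low_correlation`, `peak_mismatch`,
#'   `peaks`, `r_defined`.
#' @export
pair_expression_divergence <- function(profiles, geneA, geneB,
                                       r_threshold = 0.5, z_threshold = 1.5) {
  z <- profiles$z
  if (!all(c(geneA, geneB) %in% rownames(z))) {
    stop("pair genes missing from profiles")
  }
  za <- z[geneA, ]; zb <- z[geneB, ]
  r_defined <- !(profiles$flat[[geneA]] || profiles$flat[[geneB]])
  r <- if (r_defined) stats::cor(za, zb) else NA_real_
  spec <- stage_specificity(profiles, z_threshold)
  sa <- spec[spec$gene == geneA, ]; sb <- spec[spec$gene == geneB, ]
  peak_mismatch <- isTRUE(sa$is_stage_specific) && isTRUE(sb$is_stage_specific) &&
    sa$peak_stage != sb$peak_stage
  low_cor <- r_defined && r < r_threshold
  list(divergent = low_cor || peak_mismatch,
       r = r, low_correlation = low_cor, peak_mismatch = peak_mismatch,
       peaks = c(profiles$peak_stage[[geneA]], profiles$peak_stage[[geneB]]),
       r_defined = r_defined)
}

#' Cluster dispersion of paralogous groups
#'
#' @param assignments Named vector gene -> cluster.
#' @param paragroups List of character vectors (gene ids per paragroup).
#' @return data.frame with `paragroup`, `n_members`, `n_clusters_occupied`,
#'   `all_same_cluster`.
#' @export
paragroup_dispersion <- function(assignments, paragroups) {
  if (is.null(names(paragroups))) {
    names(paragroups) <- paste0("pg", seq_along(paragroups))
  }
  rows <- lapply(names(paragroups), function(nm) {
    g <- paragroups[[nm]]
    miss <- setdiff(g, names(assignments))
    if (length(miss)) {
      stop("paragroup member(s) missing from assignments: ",
           paste(miss, collapse = ", "))
    }
    occ <- length(unique(assignments[g]))
    data.frame(paragroup = nm, n_members = length(g),
               n_clusters_occupied = occ, all_same_cluster = occ == 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
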