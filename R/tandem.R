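## Tandem-duplication clustering of a gene family from gene order.

#' Cluster family genes into tandem arrays by intergenic distance
#'
#' Two same-chromosome family members are linked when at most `max_gap`
#' genes of the full catalog lie between them (rank difference
#' `<= max_gap + 1`); clusters are the connected components under
#' transitive chaining. Components of size one are singletons.
#'
#' @param catalog A [gene_catalog()] with the full gene order.
#' @param family Character vector of family gene ids (all must be in the
#'   catalog).
#' @param max_gap Maximum number of intervening genes (default 20).
#' @param chain Allow transitive chaining into clusters larger than two
#'   (default TRUE). With `chain = FALSE` a stricter diameter bound is used
#'   for sensitivity analysis: every pair of members in a cluster (not just
#'   consecutive ones) must satisfy the gap rule.
#' @return Object of class `tandem_clusters`: list with `clusters`
#'   (data.frame cluster_id, chrom, gene_id, rank, start, end), `singletons`
#'   (character), `max_gap`.
#' @export
cluster_tandem <- function(catalog, family, max_gap = 20L, chain = TRUE) {
  family <- unique(as.character(family))
  if (length(family) == 0) {
    return(structure(list(clusters = data.frame(), singletons = character(0),
                          max_gap = max_gap), class = "tandem_clusters"))
  }
  fam <- catalog_rank(catalog, family)
  fam <- fam[order(fam$chrom, fam$rank), ]
  comp <- integer(nrow(fam))
  cid <- 0L
  for (ch in unique(fam$chrom)) {
    idx <- which(fam$chrom == ch)
    r <- fam$rank[idx]
    brk <- c(TRUE, diff(r) > max_gap + 1L)
    grp <- cumsum(brk)
    if (!chain) {
      # diameter-bound mode: split runs whose extremes exceed the gap rule
      grp2 <- integer(length(r)); g2 <- 0L; anchor <- 1L
      for (i in seq_along(r)) {
        if (i == 1 || brk[i] || r[i] - r[anchor] > max_gap + 1L) {
          g2 <- g2 + 1L; anchor <- i
        }
        grp2[i] <- g2
      }
      grp <- grp2
    }
    comp[idx] <- cid + grp
    cid <- cid + max(grp)
  }
  sizes <- table(comp)
  singleton_comp <- as.integer(names(sizes)[sizes == 1])
  singletons <- fam$gene_id[comp %in% singleton_comp]
  keep <- !(comp %in% singleton_comp)
  clusters <- fam[keep, , drop = FALSE]
  if (nrow(clusters)) {
    clusters$cluster_id <- match(comp[keep], sort(unique(comp[keep])))
    clusters <- clusters[order(clusters$cluster_id, clusters$rank),
                         c("cluster_id", "chrom", "gene_id", "rank", "start", "end")]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(cluster_id = integer(0), chrom = character(0),
                           gene_id = character(0), rank = integer(0),
                           start = integer(0), end = integer(0))
  }
  structure(list(clusters = clusters, singletons = singletons,
                 max_gap = as.integer(max_gap)),
            class = "tandem_clusters")
}

#' @export
print.tandem_clusters <- function(x, ...) {
  ncl <- if (nrow(x$clusters)) length(unique(x$clusters$cluster_id)) else 0L
  cat(sprintf("<tandem_clusters> %d cluster(s) (%d genes), %d singleton(s), max_gap=%d\n",
              ncl, nrow(x$clusters), length(x$singletons), x$max_gap))
  invisible(x)
}

#' Single/tandem summary of a clustering
#'
#' Members of clusters of size two or more count as tandem duplicates;
#' the percentage is reported to the nearest integer.
#'
#' @param tcs A [cluster_tandem()] result.
#' @param family_size Expected family size (consistency check).
#' @return List with `n_single`, `n_tandem`, `percent_tandem`.
#' @export
summarize_tandem <- function(tcs, family_size = NULL) {
  n_tandem <- nrow(tcs$clusters)
  n_single <- length(tcs$singletons)
  total <- n_tandem + n_single
  if (!is.null(family_size) && family_size != total) {
    stop("family_size (", family_size, ") != singletons + cluster members (",
         total, ")")
  }
  list(n_single = n_single, n_tandem = n_tandem,
       percent_tandem = if (total > 0) round(100 * n_tandem / total) else 0)
}

#' Clusters with at least `min_size` members
#' @param tcs A [cluster_tandem()] result.
#' @param min_size Minimum cluster size (default 5).
#' @return data.frame of retained clusters (cluster_id, chrom, n_members,
#'   span_start, span_end), ordered by chrom then coordinate.
#' @export
big_clusters <- function(tcs, min_size = 5L) {
  cl <- tcs$clusters
  if (nrow(cl) == 0) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      n_members = integer(0), span_start = integer(0),
                      span_end = integer(0)))
  }
  agg <- do.call(rbind, lapply(split(cl, cl$cluster_id), function(d)
    data.frame(cluster_id = d$cluster_id[1], chrom = d$chrom[1],
               n_members = nrow(d), span_start = min(d$start),
               span_end = max(d$end))))
  agg <- agg[agg$n_members >= min_size, , drop = FALSE]
  agg <- agg[order(agg$chrom, agg$span_start), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Family gene density in fixed genomic windows
#'
#' Counts family genes per `window_bp` window (by gene start coordinate);
#' the last partial window is included.
#'
#' @param catalog A [gene_catalog()] with chromosome lengths.
#' @param family Family gene ids.
#' @param window_bp Window size in bp (default 1e6, a 1-Mb scale).
#' @return data.frame with `chrom`, `window_start`, `window_end`, `count`.
#' @export
density_track <- function(catalog, family, window_bp = 1e6) {
  fam <- if (length(family)) catalog_rank(catalog, family) else
    data.frame(chrom = character(0), start = integer(0))
  out <- lapply(names(catalog$chrom_lengths), function(ch) {
    len <- catalog$chrom_lengths[[ch]]
    starts <- fam$start[fam$chrom == ch]
    if (any(starts > len)) stop("gene start beyond length of ", ch)
    n_win <- ceiling(len / window_bp)
    ws <- (seq_len(n_win) - 1) * window_bp + 1
    data.frame(chrom = ch, window_start = ws,
               window_end = pmin(ws + window_bp - 1, len),
               count = vapply(seq_len(n_win), function(i)
                 sum(starts >= ws[i] & starts <= ws[i] + window_bp - 1),
                 numeric(1)))
  })
  do.call(rbind, out)
}
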