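#' Gene model: exon structure plus optional sequence
#'
#' A `gene_model` holds one gene's chromosome, strand, ordered exon intervals
#' (1-based inclusive, genomic orientation) and, optionally, the genomic
#' sequence of the gene span and the CDS sequence. It is the unit of
#' structural comparison between paralog siblings.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon `start`, `end`
#'   coordinates, 1-based inclusive, genomic order.
#' @param genomic_seq Optional DNA string covering the gene span; position 1
#'   of the string corresponds to `span(gm)[1]`.
#' @param cds_seq Optional coding sequence (transcript orientation).
#' @param cds_phase_offset Bases to trim from the CDS 5' end before
#'   translation (0-2).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       genomic_seq = NULL, cds_seq = NULL,
                       cds_phase_offset = 0L) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (nrow(exons) == 0) stop("gene ", gene_id, " has no exons")
  if (any(exons[, 1] > exons[, 2])) stop("exon start > end in ", gene_id)
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stop("overlapping exons in gene ", gene_id)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons,
         genomic_seq = if (is.null(genomic_seq)) NULL else toupper(as.character(genomic_seq)),
         cds_seq = if (is.null(cds_seq)) NULL else toupper(as.character(cds_seq)),
         cds_phase_offset = as.integer(cds_phase_offset)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s)\n",
              x$gene_id, x$chrom, x$exons[1, 1], x$exons[nrow(x$exons), 2],
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' Gene span (first exon start to last exon end)
#' @param gm A `gene_model`.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
gene_span <- function(gm) {
  unname(c(gm$exons[1, 1], gm$exons[nrow(gm$exons), 2]))
}

#' Intron intervals of a gene model
#'
#' Intron i spans `(exon_i end + 1, exon_{i+1} start - 1)`, genomic order.
#'
#' @param gm A `gene_model`.
#' @return Matrix with columns `start`, `end`; zero rows for single-exon genes.
#' @export
introns <- function(gm) {
  ex <- gm$exons
  n <- nrow(ex)
  if (n < 2) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  out <- cbind(start = ex[-n, 2] + 1L, end = ex[-1, 1] - 1L)
  if (any(out[, "end"] < out[, "start"])) {
    stop("zero-length intron in ", gm$gene_id, ": adjacent exons touch")
  }
  out
}

#' Exon/intron lengths
#' @param gm A `gene_model`.
#' @return List with integer vectors `exon` and `intron`.
#' @export
feature_lengths <- function(gm) {
  ex <- gm$exons[, 2] - gm$exons[, 1] + 1L
  intr <- introns(gm)
  list(exon = as.integer(ex),
       intron = as.integer(intr[, 2] - intr[, 1] + 1L))
}

# Sequence of a span-local interval; genomic_seq position 1 == span start.
span_subseq <- function(gm, start, end) {
  if (is.null(gm$genomic_seq)) stop("gene ", gm$gene_id, " carries no sequence")
  off <- gene_span(gm)[1] - 1L
  substr(gm$genomic_seq, start - off, end - off)
}

#' Extract exon sequences from the genomic span
#' @param gm A `gene_model` with `genomic_seq`.
#' @return Character vector of exon sequences, genomic order.
#' @export
exon_seqs <- function(gm) {
  vapply(seq_len(nrow(gm$exons)), function(i)
    span_subseq(gm, gm$exons[i, 1], gm$exons[i, 2]), character(1))
}

#' Spliced CDS from exons (reverse-complemented on the minus strand)
#' @param gm A `gene_model` with `genomic_seq`.
#' @return DNA string in transcript orientation.
#' @export
spliced_seq <- function(gm) {
  s <- paste(exon_seqs(gm), collapse = "")
  if (gm$strand == "-") s <- revcomp(s)
  if (gm$cds_phase_offset > 0) s <- substr(s, gm$cds_phase_offset + 1L, nchar(s))
  s
}

#' Ordered gene catalog for one or more chromosomes
#'
#' Stores gene order per chromosome: the substrate for tandem-duplication
#' clustering (intergenic distance in genes) and density tracks.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp;
#'   inferred from gene extents when omitted.
#' @return Object of class `gene_catalog`: the input ordered by
#'   (chrom, start), with a 0-based `rank` within each chromosome.
#' @export
gene_catalog <- function(genes, chrom_lengths = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in catalog")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), need]
  genes$rank <- unlist(lapply(split(seq_len(nrow(genes)), genes$chrom),
                              function(i) seq_along(i) - 1L), use.names = FALSE)
  # split() orders groups by chrom, matching the row order above
  rownames(genes) <- NULL
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  structure(list(genes = genes, chrom_lengths = chrom_lengths),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Look up catalog rank of genes
#' @param catalog A `gene_catalog`.
#' @param gene_ids Character vector of gene ids; all must be present.
#' @return data.frame with `gene_id`, `chrom`, `rank`, `start`, `end`.
#' @export
catalog_rank <- function(catalog, gene_ids) {
  i <- match(gene_ids, catalog$genes$gene_id)
  if (anyNA(i)) {
    stop("gene id(s) not in catalog: ",
         paste(gene_ids[is.na(i)], collapse = ", "))
  }
  catalog$genes[i, c("gene_id", "chrom", "rank", "start", "end")]
}
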