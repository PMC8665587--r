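#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and internal whitespace is removed. Duplicate
#' record ids are an error.
#'
#' @param path FASTA file.
#' @param normalize_u Replace U with T (off by default).
#' @return Named character vector id -> sequence.
#' @export
read_fasta <- function(path, normalize_u = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", as.character(ss)))
  if (normalize_u) seqs <- gsub("U", "T", seqs, fixed = TRUE)
  stats::setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read gene models and a gene catalog from GFF3
#'
#' Parses gene/mRNA/exon/CDS features. When a gene has several mRNAs, the
#' isoform with the longest total CDS is kept (ties broken by smallest
#' transcript id). Genes without mRNA children but with a `gene` feature are
#' kept in the catalog (any biotype contributes to gene order) but yield no
#' gene model. mRNAs with overlapping exons are dropped with a warning.
#'
#' @param path GFF3 file.
#' @param fasta Optional FASTA of chromosome sequences; when given, each gene
#'   model carries the genomic sequence of its span.
#' @return List with `models` (named list of [gene_model()]) and
#'   `catalog` (a [gene_catalog()]).
#' @export
read_gff3 <- function(path, fasta = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(list(models = list(),
                catalog = gene_catalog(data.frame(
                  gene_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0)))))
  }
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  chrom_seqs <- if (!is.null(fasta)) read_fasta(fasta) else NULL

  genes <- df[df$type == "gene", ]
  if (any(is.na(genes$ID))) stop("gene feature without ID")
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  if (nrow(mrnas) && any(is.na(mrnas$Parent))) stop("mRNA without Parent link")
  parts <- df[df$type %in% c("exon", "CDS"), ]
  if (nrow(parts) && any(is.na(parts$Parent))) stop("exon/CDS without Parent link")

  models <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$ID[g]
    tx <- mrnas[mrnas$Parent == gid, ]
    if (nrow(tx) == 0) next
    # pick isoform: longest total CDS, then lexicographically smallest id
    cds_len <- vapply(tx$ID, function(tid) {
      cd <- parts[parts$type == "CDS" & parts$Parent == tid, ]
      sum(cd$end - cd$start + 1L)
    }, numeric(1))
    keep <- tx$ID[order(-cds_len, tx$ID)][1]
    ex <- parts[parts$type == "exon" & parts$Parent == keep, c("start", "end")]
    if (nrow(ex) == 0) {
      ex <- parts[parts$type == "CDS" & parts$Parent == keep, c("start", "end")]
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      warning("overlapping exons in mRNA ", keep, "; record dropped")
      next
    }
    gseq <- NULL
    if (!is.null(chrom_seqs)) {
      cs <- chrom_seqs[[genes$seqnames[g]]]
      if (!is.null(cs)) gseq <- substr(cs, min(ex$start), max(ex$end))
    }
    models[[gid]] <- gene_model(gid, genes$seqnames[g],
                                if (genes$strand[g] %in% c("+", "-")) genes$strand[g] else "+",
                                ex, genomic_seq = gseq)
  }
  catalog <- gene_catalog(data.frame(
    gene_id = genes$ID, chrom = genes$seqnames,
    start = genes$start, end = genes$end,
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "+"),
    stringsAsFactors = FALSE))
  list(models = models, catalog = catalog)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features with ID/Parent links; coordinates are
#' written 1-based inclusive as stored.
#'
#' @param models List of [gene_model()].
#' @param path Output file.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    sp <- gene_span(gm)
    lines <- c(lines,
      sprintf("%s\tdupdiverge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gm$chrom, sp[1], sp[2], gm$strand, gm$gene_id),
      sprintf("%s\tdupdiverge\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              gm$chrom, sp[1], sp[2], gm$strand, gm$gene_id, gm$gene_id),
      sprintf("%s\tdupdiverge\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
              gm$chrom, gm$exons[, 1], gm$exons[, 2], gm$strand, gm$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted tree from Newick with a gene-to-species mapping
#'
#' Gene leaf labels of the form `"species|gene"` are parsed directly;
#' otherwise `species_map` must resolve every leaf. Polytomies are resolved
#' deterministically (left-to-right caterpillar via [ape::multi2di()] with
#' `random = FALSE`) and the resolution is recorded.
#'
#' @param path Newick file, or a Newick string when `text = TRUE`.
#' @param species_map Optional named character vector gene_id -> species_id.
#' @param text Treat `path` as a literal Newick string.
#' @return List of class `labeled_tree`: `tree` (an [ape::phylo]),
#'   `species_of` (named vector leaf -> species, `NULL` for species trees),
#'   `resolved_polytomy` flag.
#' @export
read_newick <- function(path, species_map = NULL, text = FALSE) {
  tr <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  resolved <- !ape::is.binary(tr) || !ape::is.rooted(tr)
  if (resolved) tr <- ape::multi2di(tr, random = FALSE)
  species_of <- NULL
  labs <- tr$tip.label
  if (any(grepl("|", labs, fixed = TRUE))) {
    sp <- sub("\\|.*$", "", labs)
    gid <- sub("^[^|]*\\|", "", labs)
    tr$tip.label <- gid
    species_of <- stats::setNames(sp, gid)
  } else if (!is.null(species_map)) {
    miss <- setdiff(labs, names(species_map))
    if (length(miss)) {
      stop("leaf label(s) not in species map: ", paste(miss, collapse = ", "))
    }
    species_of <- stats::setNames(as.character(species_map[labs]), labs)
  }
  structure(list(tree = tr, species_of = species_of,
                 resolved_polytomy = resolved),
            class = "labeled_tree")
}

#' Write a gene catalog as TSV
#' @param catalog A [gene_catalog()].
#' @param path Output file.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene catalog from TSV
#' @param path TSV with columns gene_id, chrom, start, end, strand.
#' @return A [gene_catalog()].
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_catalog(df)
}
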