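## End-to-end orchestration: simulate a full synthetic dataset to disk,
## run every analysis stage on a dataset directory, and record a
## reproducibility manifest.

#' Write a complete synthetic dataset with ground truth to a directory
#'
#' Generates every input the pipeline consumes: a gene catalog with a
#' planted tandem-clustered family, gene trees simulated along a species
#' tree, paralog sibling pairs with planted structural mechanisms (as GFF3 +
#' FASTA), codon pairs evolved at set dN/dS values (FASTA + pairs TSV), a
#' stage-profiled expression matrix (TSV), and a repeat-bearing sequence.
#' A `ground_truth.json` sidecar records every planted feature.
#'
#' @param dir Output directory (created).
#' @param seed RNG seed; the whole dataset is a pure function of it.
#' @param n_struct_pairs Structural pairs per mechanism (default 2).
#' @param n_families Gene families to simulate (default 30).
#' @return Invisibly, the ground-truth list.
#' @export
sim_dataset <- function(dir, seed = 1L, n_struct_pairs = 2L, n_families = 30L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genetrees"), showWarnings = FALSE)
  with_seed(seed, {
    gt <- list(seed = seed)

    cat_sim <- sim_catalog_with_family(
      n_chroms = 2L, genes_per_chrom = 150L, family_size = 14L,
      planted_clusters = data.frame(chrom = c(1L, 2L), start_rank = c(10L, 40L),
                                    size = c(6L, 4L), max_internal_gap = c(5L, 10L)))
    write_catalog_tsv(cat_sim$catalog, file.path(dir, "catalog.tsv"))
    writeLines(cat_sim$family, file.path(dir, "family_ids.txt"))
    gt$tandem <- cat_sim$truth

    sp_nwk <- "((((Cbn,Cre),(Cbr,Cel)),Cja),Ppa);"
    writeLines(sp_nwk, file.path(dir, "species_tree.nwk"))
    forest <- sim_gene_trees_dl(sp_nwk, dup_rate = 0.4, loss_rate = 0.1,
                                n_families = n_families)
    for (i in seq_along(forest$gene_trees)) {
      phy <- relabel_with_species(forest$gene_trees[[i]]$tree,
                                  forest$gene_trees[[i]]$species_of)
      ape::write.tree(phy, file.path(dir, "genetrees", sprintf("fam%03d.nwk", i)))
    }
    gt$reconcile <- forest$truth

    mechs <- c("NONE", "EXON_INTRON_GAIN_LOSS", "INTRON_ELONGATION",
               "EXONIZATION", "BOUNDARY_SHIFT", "EXON_SPLIT")
    models <- list(); pair_rows <- list(); struct_truth <- list()
    k <- 0L
    for (m in mechs) for (r in seq_len(n_struct_pairs)) {
      k <- k + 1L
      pr <- sim_paralog_pair(m, pair_id = sprintf("sp%02d", k))
      models[[pr$A$gene_id]] <- pr$A
      models[[pr$B$gene_id]] <- pr$B
      pair_rows[[k]] <- data.frame(geneA = pr$A$gene_id, geneB = pr$B$gene_id)
      struct_truth[[k]] <- list(geneA = pr$A$gene_id, geneB = pr$B$gene_id,
                                mechanism = m)
    }
    write_gff3(models, file.path(dir, "struct_pairs.gff3"))
    write_fasta(vapply(models, `[[`, "", "genomic_seq"),
                file.path(dir, "struct_pairs.fa"))
    utils::write.table(do.call(rbind, pair_rows),
                       file.path(dir, "struct_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt$structdiv <- struct_truth

    omegas <- c(0.1, 0.3, 1.0)
    cds <- character(0); dnds_rows <- list(); dnds_truth <- list()
    for (i in seq_along(omegas)) {
      cp <- sim_codon_pair(200L, omegas[i], n_attempts = 60L)
      ida <- sprintf("cds%02d_A", i); idb <- sprintf("cds%02d_B", i)
      cds[ida] <- cp$cdsA; cds[idb] <- cp$cdsB
      dnds_rows[[i]] <- data.frame(seqA = ida, seqB = idb)
      dnds_truth[[i]] <- list(seqA = ida, seqB = idb, nominal_omega = omegas[i],
                              n_syn = cp$n_syn, n_nonsyn = cp$n_nonsyn)
    }
    write_fasta(cds, file.path(dir, "cds_pairs.fa"))
    utils::write.table(do.call(rbind, dnds_rows), file.path(dir, "cds_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt$selection <- dnds_truth

    stages <- c("EE", "LE", "L1", "L2", "L3", "L4", "YA")
    ex <- sim_expression(stages, n_genes = 120L, k = 8L, noise_sd = 0.2,
                         pair_plan = c(concordant = 8L, divergent = 8L))
    utils::write.table(data.frame(gene = rownames(ex$matrix),
                                  round(ex$matrix, 4), check.names = FALSE),
                       file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ex$pairs, file.path(dir, "expression_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt$expression <- list(archetypes = ex$truth, pairs = ex$pairs)

    rp <- sim_repeat_sequence(unit_len = 50L, n_copies = 6L, flank_len = 500L)
    write_fasta(c(repeat_seq = rp$seq), file.path(dir, "repeat_seq.fa"))
    gt$dotplot <- rp$truth

    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(gt)
  })
}

relabel_with_species <- function(phy, species_of) {
  phy$tip.label <- paste0(species_of[phy$tip.label], "|", phy$tip.label)
  phy
}

#' Run every analysis stage on a dataset directory
#'
#' Executes, in dependency order, whichever stages have inputs present in
#' `dataset_dir` (as written by [sim_dataset()] or assembled by hand):
#' tandem clustering, reconciliation, structural classification, dot-plot
#' repeat detection, dN/dS, and expression analysis. Writes one TSV per
#' stage under `out_dir` plus a `manifest.json` with input digests, the
#' seed, and per-output row counts. Identical inputs and seed reproduce
#' byte-identical outputs.
#'
#' @param dataset_dir Directory of inputs.
#' @param out_dir Output directory (created).
#' @param seed Seed used for the seeded stages (expression clustering).
#' @param max_gap,k Stage parameters (tandem gap rule; expression clusters).
#' @return The manifest, invisibly.
#' @export
run_all <- function(dataset_dir, out_dir, seed = 1L, max_gap = 20L, k = 8L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dataset_dir, ...)
  outputs <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- nrow(df)
    path
  }

  if (file.exists(p("catalog.tsv")) && file.exists(p("family_ids.txt"))) {
    catalog <- read_catalog_tsv(p("catalog.tsv"))
    family <- readLines(p("family_ids.txt"))
    tcs <- cluster_tandem(catalog, family, max_gap = max_gap)
    smry <- summarize_tandem(tcs)
    emit(tcs$clusters, "tandem_clusters.tsv")
    emit(data.frame(n_single = smry$n_single, n_tandem = smry$n_tandem,
                    percent_tandem = smry$percent_tandem), "tandem_summary.tsv")
    emit(density_track(catalog, family), "density_track.tsv")
  }

  if (file.exists(p("species_tree.nwk")) && dir.exists(p("genetrees"))) {
    sp <- read_newick(p("species_tree.nwk"))
    files <- sort(list.files(p("genetrees"), full.names = TRUE))
    recons <- lapply(files, function(f) lca_reconcile(read_newick(f), sp))
    hist <- aggregate_histories(recons, sp)
    emit(as.data.frame(hist), "family_history.tsv")
  }

  if (file.exists(p("struct_pairs.gff3")) && file.exists(p("struct_pairs.tsv"))) {
    gm <- read_gff3(p("struct_pairs.gff3"), fasta = p("struct_pairs.fa"))
    pairs <- utils::read.table(p("struct_pairs.tsv"), header = TRUE,
                               stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- gm$models[[pairs$geneA[i]]]; b <- gm$models[[pairs$geneB[i]]]
      dv <- classify_pair(build_correspondence(a, b), a, b)
      data.frame(geneA = a$gene_id, geneB = b$gene_id,
                 primary = dv$primary, n_events = nrow(dv$events))
    })
    emit(do.call(rbind, rows), "structdiv.tsv")
  }

  if (file.exists(p("repeat_seq.fa"))) {
    seqs <- read_fasta(p("repeat_seq.fa"))
    rows <- lapply(names(seqs), function(id) {
      calls <- call_repeats(self_dot_matrix(seqs[[id]]))
      if (nrow(calls) == 0) return(NULL)
      cbind(seq_id = id, as.data.frame(calls))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    emit(if (length(rows)) do.call(rbind, rows) else
      data.frame(seq_id = character(0)), "repeat_calls.tsv")
  }

  if (file.exists(p("cds_pairs.fa")) && file.exists(p("cds_pairs.tsv"))) {
    cds <- read_fasta(p("cds_pairs.fa"))
    pairs <- utils::read.table(p("cds_pairs.tsv"), header = TRUE,
                               stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      r <- pairwise_dnds(cds[[pairs$seqA[i]]], cds[[pairs$seqB[i]]])
      data.frame(seqA = pairs$seqA[i], seqB = pairs$seqB[i],
                 S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
                 dS = r$dS, dN = r$dN, omega = r$omega)
    })
    emit(do.call(rbind, rows), "dnds.tsv")
  }

  if (file.exists(p("expression.tsv"))) {
    tab <- utils::read.table(p("expression.tsv"), header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, -1]); rownames(mat) <- tab[[1]]
    prof <- zscore_profiles(mat)
    cl <- cluster_stage_patterns(prof, k = k, seed = seed)
    spec <- stage_specificity(prof)
    emit(data.frame(gene = names(cl), cluster = unname(cl),
                    is_stage_specific = spec$is_stage_specific,
                    peak_stage = prof$peak_stage[names(cl)]),
         "expression_clusters.tsv")
    if (file.exists(p("expression_pairs.tsv"))) {
      pr <- utils::read.table(p("expression_pairs.tsv"), header = TRUE,
                              stringsAsFactors = FALSE)
      rows <- lapply(seq_len(nrow(pr)), function(i) {
        d <- pair_expression_divergence(prof, pr$geneA[i], pr$geneB[i])
        data.frame(geneA = pr$geneA[i], geneB = pr$geneB[i],
                   divergent = d$divergent, r = d$r,
                   peak_mismatch = d$peak_mismatch)
      })
      emit(do.call(rbind, rows), "expression_divergence.tsv")
    }
  }

  inputs <- list.files(dataset_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    tool = "dupdiverge",
    version = as.character(utils::packageVersion("dupdiverge")),
    seed = seed,
    parameters = list(max_gap = max_gap, k = k),
    input_digests = as.list(tools::md5sum(inputs)),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
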