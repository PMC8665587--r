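## Synthetic-data generators with planted ground truth for every pipeline
## stage: gene catalogs with tandem clusters, paralog pairs with one planted
## structural-divergence mechanism, codon pairs evolved at a target dN/dS,
## birth-death gene trees with recorded events, repeat-bearing DNA, and
## stage-profiled expression matrices.

# Run expr under a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a gene catalog with a planted tandem-clustered family
#'
#' Places family genes at planted ranks forming tandem clusters, and the
#' remaining family members as singletons at least `max_gap + 1` genes away
#' from any other family member.
#'
#' @param n_chroms Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome (scalar or vector).
#' @param family_size Total family size (clustered + singleton members).
#' @param planted_clusters data.frame with columns `chrom` (1-based index),
#'   `start_rank` (0-based), `size`, `max_internal_gap` (genes between
#'   consecutive members).
#' @param max_gap Gap rule the singletons must respect (default 20).
#' @param gene_len,gene_gap Gene length and intergenic spacing in bp.
#' @param seed RNG seed.
#' @return List with `catalog` ([gene_catalog()]), `family` (ids) and
#'   `truth` (data.frame `gene_id`, `chrom`, `rank`, `cluster`; `NA` cluster
#'   = planted singleton).
#' @export
sim_catalog_with_family <- function(n_chroms = 1L, genes_per_chrom = 100L,
                                    family_size, planted_clusters,
                                    max_gap = 20L, gene_len = 1000L,
                                    gene_gap = 1000L, seed = NULL) {
  with_seed(seed, {
    gpc <- rep_len(genes_per_chrom, n_chroms)
    chroms <- sprintf("chr%d", seq_len(n_chroms))
    # planted ranks per chromosome
    fam_pos <- list()  # list of (chrom_idx, rank, cluster_id)
    if (!is.null(planted_clusters) && nrow(planted_clusters)) {
      for (ci in seq_len(nrow(planted_clusters))) {
        pc <- planted_clusters[ci, ]
        gaps <- if (pc$size > 1 && pc$max_internal_gap > 0)
          sample(0:pc$max_internal_gap, pc$size - 1, replace = TRUE) else rep(0L, max(pc$size - 1, 0))
        ranks <- pc$start_rank + cumsum(c(0L, gaps + 1L))
        if (any(ranks >= gpc[pc$chrom])) {
          stop("planted cluster ", ci, " does not fit on chromosome ", pc$chrom)
        }
        fam_pos[[length(fam_pos) + 1L]] <-
          data.frame(chrom = pc$chrom, rank = ranks, cluster = ci)
      }
    }
    fam_pos <- if (length(fam_pos)) do.call(rbind, fam_pos) else
      data.frame(chrom = integer(0), rank = integer(0), cluster = integer(0))
    if (anyDuplicated(fam_pos[c("chrom", "rank")])) {
      stop("planted clusters overlap")
    }
    n_clustered <- nrow(fam_pos)
    n_singleton <- family_size - n_clustered
    if (n_singleton < 0) stop("family_size smaller than planted cluster total")
    # singleton placement: any rank >= max_gap+1 away from all family ranks
    for (s in seq_len(n_singleton)) {
      placed <- FALSE
      for (ch in sample(seq_len(n_chroms))) {
        taken <- fam_pos$rank[fam_pos$chrom == ch]
        ok <- setdiff(0:(gpc[ch] - 1L), unlist(lapply(taken, function(r)
          (r - max_gap - 1L):(r + max_gap + 1L))))
        if (length(ok)) {
          fam_pos <- rbind(fam_pos, data.frame(
            chrom = ch, rank = pick1(ok),
            cluster = NA_integer_))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("cannot place singleton ", s,
                        " with the required separation; enlarge the catalog")
    }
    # build the catalog
    rows <- list(); truth <- list(); fam_i <- 0L
    for (ch in seq_len(n_chroms)) {
      ranks <- 0:(gpc[ch] - 1L)
      here <- fam_pos[fam_pos$chrom == ch, ]
      ids <- sprintf("bg_%s_g%04d", chroms[ch], ranks)
      for (k in seq_len(nrow(here))) {
        fam_i <- fam_i + 1L
        ids[here$rank[k] + 1L] <- sprintf("fam%03d", fam_i)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = sprintf("fam%03d", fam_i), chrom = chroms[ch],
          rank = here$rank[k], cluster = here$cluster[k])
      }
      start <- ranks * (gene_len + gene_gap) + 1L
      rows[[ch]] <- data.frame(
        gene_id = ids, chrom = chroms[ch], start = start,
        end = start + gene_len - 1L,
        strand = sample(c("+", "-"), gpc[ch], replace = TRUE),
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), chrom = character(0),
                 rank = integer(0), cluster = integer(0))
    chrom_lengths <- stats::setNames(as.integer(gpc * (gene_len + gene_gap)), chroms)
    list(catalog = gene_catalog(genes, chrom_lengths),
         family = truth$gene_id, truth = truth)
  })
}

## ---- paralog-pair simulator ------------------------------------------------

# internal: gene as alternating segment list exon/intron
segs_from_lens <- function(exon_lens, intron_lens) {
  segs <- list()
  for (i in seq_along(exon_lens)) {
    segs[[length(segs) + 1L]] <- list(type = "exon", seq = random_dna(exon_lens[i]))
    if (i < length(exon_lens)) {
      segs[[length(segs) + 1L]] <- list(type = "intron", seq = random_dna(intron_lens[i]))
    }
  }
  segs
}

segs_to_model <- function(segs, gene_id, chrom = gene_id, strand = "+") {
  pos <- 1L; ex <- NULL; seqs <- character(0)
  for (s in segs) {
    len <- nchar(s$seq)
    if (s$type == "exon") ex <- rbind(ex, c(pos, pos + len - 1L))
    seqs <- c(seqs, s$seq)
    pos <- pos + len
  }
  gene_model(gene_id, chrom, strand, ex, genomic_seq = paste(seqs, collapse = ""))
}

exon_idx <- function(segs) which(vapply(segs, `[[`, "", "type") == "exon")
intron_idx <- function(segs) which(vapply(segs, `[[`, "", "type") == "intron")

#' Simulate a paralog sibling pair with one planted divergence mechanism
#'
#' Gene B is derived from gene A by iid point mutations plus one planted
#' structural event: gain/loss of an exon, substantial intron elongation via
#' inserted ~50 bp tandem repeats, exonization/pseudoexonization (an exon
#' homolog ending up inside an intron), a splice-boundary shift, or an exon
#' split by a novel intron.
#'
#' @param mechanism One of `"NONE"`, `"EXON_INTRON_GAIN_LOSS"`,
#'   `"INTRON_ELONGATION"`, `"EXONIZATION"`, `"BOUNDARY_SHIFT"`,
#'   `"EXON_SPLIT"`.
#' @param n_exons Number of exons in gene A (default 5).
#' @param exon_len,intron_len Length ranges (bp) for exons and introns.
#' @param mutation_rate Per-site point-mutation rate applied to B (default
#'   0.05).
#' @param elongation_factor Target intron length multiplier for
#'   `INTRON_ELONGATION` (default 6; must exceed 2).
#' @param repeat_unit_len Repeat unit length used to elongate (default 50).
#' @param boundary_offset Splice-boundary shift in bp (default 9).
#' @param split_intron_len Length of the novel intron for `EXON_SPLIT`
#'   (default 90).
#' @param pair_id Identifier prefix for the two genes.
#' @param seed RNG seed.
#' @return List with `A`, `B` ([gene_model()]s with sequence) and `truth`
#'   (list: `mechanism` plus event coordinates/parameters).
#' @export
sim_paralog_pair <- function(mechanism = "NONE", n_exons = 5L,
                             exon_len = c(100L, 300L), intron_len = c(80L, 200L),
                             mutation_rate = 0.05, elongation_factor = 6,
                             repeat_unit_len = 50L, boundary_offset = 9L,
                             split_intron_len = 90L, pair_id = "pair",
                             seed = NULL) {
  mech <- match.arg(mechanism, c("NONE", "EXON_INTRON_GAIN_LOSS",
                                 "INTRON_ELONGATION", "EXONIZATION",
                                 "BOUNDARY_SHIFT", "EXON_SPLIT"))
  rint <- function(rng, n) {
    if (rng[1] == rng[2]) rep(as.integer(rng[1]), n)
    else sample(rng[1]:rng[2], n, replace = TRUE)
  }
  with_seed(seed, {
    exl <- rint(exon_len, n_exons)
    inl <- rint(intron_len, n_exons - 1L)
    segsA <- segs_from_lens(exl, inl)
    segsB <- segsA
    truth <- list(mechanism = mech)

    if (mech == "EXON_INTRON_GAIN_LOSS") {
      if (stats::runif(1) < 0.5 && n_exons >= 3) {
        # loss: remove an internal exon and its following intron from B
        ei <- exon_idx(segsB)
        tgt <- pick1(ei[-c(1, length(ei))])
        segsB <- segsB[-c(tgt, tgt + 1L)]
        truth$event <- "exon_loss_in_B"
        truth$exon_A <- which(ei == tgt)
      } else {
        # gain: insert a novel exon inside an intron of B
        ii <- intron_idx(segsB)
        tgt <- pick1(ii)
        intr <- segsB[[tgt]]$seq
        half <- nchar(intr) %/% 2
        new_exon <- random_dna(rint(exon_len, 1))
        segsB <- append(segsB[-tgt], list(
          list(type = "intron", seq = substr(intr, 1, half)),
          list(type = "exon", seq = new_exon),
          list(type = "intron", seq = substr(intr, half + 1L, nchar(intr)))),
          after = tgt - 1L)
        truth$event <- "exon_gain_in_B"
        truth$intron_A <- which(intron_idx(segsA) == tgt)
      }
    } else if (mech == "INTRON_ELONGATION") {
      if (elongation_factor <= 2) stop("elongation_factor must exceed 2")
      ii <- intron_idx(segsB)
      tgt <- pick1(ii)
      old <- segsB[[tgt]]$seq
      extra <- ceiling((elongation_factor - 1) * nchar(old))
      unit <- random_dna(repeat_unit_len)
      n_copies <- ceiling(extra / repeat_unit_len)
      ins <- paste(vapply(seq_len(n_copies), function(i)
        mutate_dna(unit, 0.02), character(1)), collapse = "")
      half <- nchar(old) %/% 2
      segsB[[tgt]]$seq <- paste0(substr(old, 1, half), ins,
                                 substr(old, half + 1L, nchar(old)))
      truth$event <- "intron_elongation_in_B"
      truth$intron_A <- which(intron_idx(segsA) == tgt)
      truth$ratio <- nchar(segsB[[tgt]]$seq) / nchar(old)
      truth$repeat_unit_len <- repeat_unit_len
    } else if (mech == "EXONIZATION") {
      if (n_exons < 3) stop("exonization needs an internal exon")
      ei <- exon_idx(segsB)
      tgt <- pick1(ei[-c(1, length(ei))])
      merged <- paste0(segsB[[tgt - 1L]]$seq, segsB[[tgt]]$seq,
                       segsB[[tgt + 1L]]$seq)
      segsB <- append(segsB[-((tgt - 1L):(tgt + 1L))],
                      list(list(type = "intron", seq = merged)),
                      after = tgt - 2L)
      truth$event <- "exon_of_A_intronic_in_B"
      truth$exon_A <- which(ei == tgt)
    } else if (mech == "BOUNDARY_SHIFT") {
      ei <- exon_idx(segsB)
      # pick an exon with an adjacent intron; shift the shared boundary
      cand <- ei[ei > 1 | ei < length(segsB)]
      tgt <- pick1(cand)
      left <- tgt > 1 && (tgt == length(segsB) || stats::runif(1) < 0.5)
      o <- boundary_offset
      grow <- stats::runif(1) < 0.5  # exon grows into the intron, or shrinks
      if (left) {
        intr <- segsB[[tgt - 1L]]$seq; exn <- segsB[[tgt]]$seq
        if (grow) {
          take <- substr(intr, nchar(intr) - o + 1L, nchar(intr))
          segsB[[tgt - 1L]]$seq <- substr(intr, 1, nchar(intr) - o)
          segsB[[tgt]]$seq <- paste0(take, exn)
        } else {
          give <- substr(exn, 1, o)
          segsB[[tgt]]$seq <- substr(exn, o + 1L, nchar(exn))
          segsB[[tgt - 1L]]$seq <- paste0(intr, give)
        }
      } else {
        exn <- segsB[[tgt]]$seq; intr <- segsB[[tgt + 1L]]$seq
        if (grow) {
          take <- substr(intr, 1, o)
          segsB[[tgt + 1L]]$seq <- substr(intr, o + 1L, nchar(intr))
          segsB[[tgt]]$seq <- paste0(exn, take)
        } else {
          give <- substr(exn, nchar(exn) - o + 1L, nchar(exn))
          segsB[[tgt]]$seq <- substr(exn, 1, nchar(exn) - o)
          segsB[[tgt + 1L]]$seq <- paste0(give, intr)
        }
      }
      truth$event <- "boundary_shift_in_B"
      truth$exon_A <- which(ei == tgt)
      truth$offset <- o * (if (grow) 1L else -1L)
      truth$side <- if (left) "5prime" else "3prime"
    } else if (mech == "EXON_SPLIT") {
      min_piece <- 40L
      ei <- exon_idx(segsB)
      lens <- vapply(segsB[ei], function(s) nchar(s$seq), integer(1))
      ok <- ei[lens >= 2L * min_piece]
      if (!length(ok)) stop("no exon long enough to split")
      tgt <- pick1(ok)
      exn <- segsB[[tgt]]$seq
      at <- pick1(min_piece:(nchar(exn) - min_piece))
      segsB <- append(segsB[-tgt], list(
        list(type = "exon", seq = substr(exn, 1, at)),
        list(type = "intron", seq = random_dna(split_intron_len)),
        list(type = "exon", seq = substr(exn, at + 1L, nchar(exn)))),
        after = tgt - 1L)
      truth$event <- "exon_split_in_B"
      truth$exon_A <- which(ei == tgt)
      truth$split_offset <- at
      truth$novel_intron_len <- split_intron_len
    }

    # iid point mutations on every B segment
    if (mutation_rate > 0) {
      segsB <- lapply(segsB, function(s) {
        s$seq <- mutate_dna(s$seq, mutation_rate); s
      })
    }
    list(A = segs_to_model(segsA, paste0(pair_id, "_A")),
         B = segs_to_model(segsB, paste0(pair_id, "_B")),
         truth = truth)
  })
}

#' Simulate a codon-sequence pair evolved at a target dN/dS
#'
#' Starting from a random stop-free codon sequence, `n_attempts` single-base
#' changes are proposed (uniform site, uniform alternative base). Proposals
#' creating stop codons are rejected; synonymous proposals are always
#' accepted, nonsynonymous ones with probability `min(1, omega)`. The
#' realized substitutions are recorded, so the realized (not nominal) dN/dS
#' is known exactly.
#'
#' @param n_codons Sequence length in codons (>= 15).
#' @param omega Target dN/dS (>= 0).
#' @param n_attempts Number of proposed mutations.
#' @param seed RNG seed.
#' @return List with `cdsA`, `cdsB`, `substitutions` (data.frame `site`,
#'   `from_codon`, `to_codon`, `type`), `n_syn`, `n_nonsyn`.
#' @export
sim_codon_pair <- function(n_codons, omega, n_attempts, seed = NULL) {
  if (n_codons < 15) stop("n_codons must be at least 15")
  if (omega < 0) stop("omega must be >= 0")
  with_seed(seed, {
    sense <- names(genetic_code())[genetic_code() != "*"]
    codons <- sample(sense, n_codons, replace = TRUE)
    a <- paste(codons, collapse = "")
    v <- strsplit(a, "")[[1]]
    subs <- list()
    for (t in seq_len(n_attempts)) {
      site <- sample.int(length(v), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), v[site]), 1)
      ci <- (site - 1L) %/% 3L
      old_codon <- paste(v[ci * 3L + 1:3], collapse = "")
      w <- v; w[site] <- b
      new_codon <- paste(w[ci * 3L + 1:3], collapse = "")
      if (is_stop(new_codon)) next
      syn <- translate_codon(new_codon) == translate_codon(old_codon)
      if (syn || stats::runif(1) < min(1, omega)) {
        v <- w
        subs[[length(subs) + 1L]] <- data.frame(
          site = site, from_codon = old_codon, to_codon = new_codon,
          type = if (syn) "synonymous" else "nonsynonymous",
          stringsAsFactors = FALSE)
      }
    }
    subs <- if (length(subs)) do.call(rbind, subs) else
      data.frame(site = integer(0), from_codon = character(0),
                 to_codon = character(0), type = character(0))
    list(cdsA = a, cdsB = paste(v, collapse = ""),
         substitutions = subs,
         n_syn = sum(subs$type == "synonymous"),
         n_nonsyn = sum(subs$type == "nonsynonymous"))
  })
}

#' Simulate gene families along a species tree under birth-death
#'
#' Each family starts as one lineage entering the species-tree root. On
#' every branch (including a virtual branch above the root) a lineage is
#' lost with probability `1 - exp(-loss_rate)`; a surviving lineage
#' acquires `k ~ Poisson(dup_rate)` duplications on that branch. Families
#' with fewer than two surviving genes are discarded (and counted).
#'
#' @param species_tree Rooted binary species tree (`phylo`, `labeled_tree`
#'   or Newick string).
#' @param dup_rate,loss_rate Per-branch event rates (>= 0).
#' @param n_families Number of families to simulate.
#' @param seed RNG seed.
#' @return List with `gene_trees` (list of `labeled_tree`), `truth`
#'   (data.frame `family`, `branch` — label of the species node whose
#'   entering branch carries the event —, `dups`, `losses`),
#'   `n_discarded`.
#' @export
sim_gene_trees_dl <- function(species_tree, dup_rate, loss_rate,
                              n_families, seed = NULL) {
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  sphy <- if (is.character(species_tree))
    ape::read.tree(text = species_tree) else as_phylo_tree(species_tree)
  if (!ape::is.binary(sphy)) stop("species tree must be binary")
  sidx <- tree_index(sphy)
  p_loss <- 1 - exp(-loss_rate)
  with_seed(seed, {
    gene_trees <- list(); truth <- list(); n_discarded <- 0L
    for (f in seq_len(n_families)) {
      dups <- integer(sidx$n_nodes); losses <- integer(sidx$n_nodes)
      leaf_n <- 0L
      # returns a Newick fragment for one lineage entering the branch to v,
      # or NULL if nothing survives below
      enter <- function(v) {
        if (stats::runif(1) < p_loss) {
          losses[v] <<- losses[v] + 1L
          return(NULL)
        }
        k <- stats::rpois(1, dup_rate)
        dups[v] <<- dups[v] + k
        copies <- lapply(seq_len(k + 1L), function(i) at_node(v))
        copies <- copies[!vapply(copies, is.null, logical(1))]
        if (!length(copies)) {
          # every copy died below: the planted duplications on this branch
          # left no trace; drop them from the recorded truth
          dups[v] <<- dups[v] - k
          return(NULL)
        }
        sub <- copies[[1]]
        for (c2 in copies[-1]) sub <- paste0("(", sub, ",", c2, ")")
        sub
      }
      at_node <- function(v) {
        if (v <= sidx$ntip) {
          leaf_n <<- leaf_n + 1L
          return(sprintf("%s|%s_g%d", sidx$label[v], sprintf("fam%d", f), leaf_n))
        }
        ch <- sidx$children[[v]]
        l <- enter(ch[1]); r <- enter(ch[2])
        if (is.null(l) && is.null(r)) return(NULL)
        if (is.null(l)) return(r)
        if (is.null(r)) return(l)
        paste0("(", l, ",", r, ")")
      }
      nwk <- enter(sidx$root)
      if (is.null(nwk) || leaf_n < 2L || !grepl(",", nwk)) {
        n_discarded <- n_discarded + 1L
        next
      }
      gene_trees[[length(gene_trees) + 1L]] <-
        read_newick(paste0(nwk, ";"), text = TRUE)
      ev <- which(dups > 0 | losses > 0)
      if (length(ev)) {
        truth[[length(truth) + 1L]] <- data.frame(
          family = length(gene_trees), branch = sidx$label[ev],
          dups = dups[ev], losses = losses[ev], stringsAsFactors = FALSE)
      }
    }
    if (!length(gene_trees)) stop("all families extinct; lower loss_rate")
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(family = integer(0), branch = character(0),
                 dups = integer(0), losses = integer(0))
    list(gene_trees = gene_trees, truth = truth, n_discarded = n_discarded)
  })
}

#' Simulate a stage-profiled expression matrix with planted structure
#'
#' Each gene follows one of `k` archetype profiles on the log2 scale: one
#' high-expression peak per stage, plus a flat-low archetype when
#' `k = n_stages + 1`. Gaussian noise of sd `noise_sd` is added on the log
#' scale and values are mapped back to an FPKM-like scale. Optional paralog
#' pairs are generated concordant (same archetype) or divergent (different
#' peak stages).
#'
#' @param stages Character vector of stage labels.
#' @param n_genes Number of unpaired genes.
#' @param k Number of archetypes (`<= length(stages) + 1`).
#' @param noise_sd Log-scale noise sd (>= 0).
#' @param pair_plan Optional named vector, e.g.
#'   `c(concordant = 10, divergent = 10)`.
#' @param seed RNG seed.
#' @param peak_log2,base_log2 Peak and baseline log2 expression levels.
#' @return List with `matrix` (genes x stages, FPKM-like), `truth`
#'   (data.frame `gene`, `archetype`, `peak_stage`) and `pairs` (data.frame
#'   `geneA`, `geneB`, `divergent`).
#' @export
sim_expression <- function(stages, n_genes, k, noise_sd, pair_plan = NULL,
                           seed = NULL, peak_log2 = 8, base_log2 = 2) {
  S <- length(stages)
  if (k > S + 1) stop("k exceeds the number of constructible archetypes (stages + flat)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    archetype_mean <- function(a) {
      m <- rep(base_log2, S)
      if (a <= S) m[a] <- peak_log2
      m
    }
    gene_row <- function(a) {
      x <- archetype_mean(a) + stats::rnorm(S, 0, noise_sd)
      pmax(2^x - 1, 0)
    }
    arch <- sample.int(k, n_genes, replace = TRUE)
    genes <- sprintf("g%04d", seq_len(n_genes))
    mat <- t(vapply(arch, gene_row, numeric(S)))
    pairs <- data.frame(geneA = character(0), geneB = character(0),
                        divergent = logical(0))
    if (!is.null(pair_plan) && sum(pair_plan) > 0) {
      pa <- c(rep(FALSE, pair_plan[["concordant"]] %||% 0),
              rep(TRUE, pair_plan[["divergent"]] %||% 0))
      for (i in seq_along(pa)) {
        if (pa[i]) {
          ab <- sample.int(S, 2)  # two distinct peak archetypes
        } else {
          ab <- rep(sample.int(S, 1), 2)
        }
        ga <- sprintf("pair%03d_A", i); gb <- sprintf("pair%03d_B", i)
        mat <- rbind(mat, gene_row(ab[1]), gene_row(ab[2]))
        genes <- c(genes, ga, gb)
        arch <- c(arch, ab)
        pairs <- rbind(pairs, data.frame(geneA = ga, geneB = gb,
                                         divergent = pa[i]))
      }
    }
    rownames(mat) <- genes
    colnames(mat) <- stages
    truth <- data.frame(gene = genes, archetype = arch,
                        peak_stage = ifelse(arch <= S, stages[pmin(arch, S)], "flat"),
                        stringsAsFactors = FALSE)
    list(matrix = mat, truth = truth, pairs = pairs)
  })
}

#' Simulate a DNA sequence carrying a planted tandem repeat
#'
#' Random flank, `n_copies` tandem copies of a random `unit_len`-bp unit
#' (each copy independently mutated at `mutation_rate`), random flank.
#'
#' @param unit_len Repeat unit length (>= 10).
#' @param n_copies Number of copies (>= 2).
#' @param flank_len Flank length on both sides.
#' @param mutation_rate Per-site mutation rate per copy (<= 0.3).
#' @param seed RNG seed.
#' @return List with `seq` and `truth` (`unit_len`, `start`, `end`).
#' @export
sim_repeat_sequence <- function(unit_len = 50L, n_copies = 6L,
                                flank_len = 500L, mutation_rate = 0.02,
                                seed = NULL) {
  if (unit_len < 10) stop("unit_len must be >= 10")
  if (n_copies < 2) stop("n_copies must be >= 2")
  if (mutation_rate > 0.3) stop("mutation_rate above the supported maximum (0.3)")
  with_seed(seed, {
    unit <- random_dna(unit_len)
    copies <- vapply(seq_len(n_copies), function(i)
      mutate_dna(unit, mutation_rate), character(1))
    seq <- paste0(random_dna(flank_len), paste(copies, collapse = ""),
                  random_dna(flank_len))
    list(seq = seq,
         truth = list(unit_len = unit_len, start = flank_len + 1L,
                      end = flank_len + n_copies * unit_len))
  })
}
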