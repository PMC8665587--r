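## Exon/intron structural-divergence classification between closely related
## paralog siblings: exon-level local alignment, exon correspondence, and a
## five-mechanism rule set.

#' Local alignment of an exon against a sibling's genomic span
#'
#' Smith-Waterman local alignment with affine gaps (match +2, mismatch -3,
#' gap open -5, gap extend -2 per base; a length-L gap costs
#' `open + L * extend`). Ties are broken deterministically by the alignment
#' engine; coordinates are reported 1-based inclusive in the subject.
#'
#' @param exon_seq Exon sequence (query).
#' @param gene_genomic_seq Genomic span of the sibling gene (subject).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (positive
#'   costs for the gap terms).
#' @return List with `score`, `start`, `end` (subject coords),
#'   `q_start`, `q_end` (query coords), `identity` (matches / alignment
#'   columns), `n_match`, `aligned_length` (alignment columns).
#' @export
align_exon_to_gene <- function(exon_seq, gene_genomic_seq,
                               match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  check_dna(toupper(exon_seq), "exon sequence")
  check_dna(toupper(gene_genomic_seq), "genomic sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(exon_seq)),
    Biostrings::DNAString(toupper(gene_genomic_seq)),
    type = "local", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  sub <- Biostrings::subject(pa)
  pat <- Biostrings::pattern(pa)
  ncols <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  list(score = Biostrings::score(pa),
       start = IRanges::start(sub), end = IRanges::end(sub),
       q_start = IRanges::start(pat), q_end = IRanges::end(pat),
       identity = if (ncols > 0) nm / ncols else 0,
       n_match = nm, aligned_length = ncols)
}

#' Exon correspondence between two gene models
#'
#' Aligns every exon of each gene against the full genomic span of the
#' other. Alignments shorter than `min_length` or below `min_identity` are
#' discarded ("no counterpart"). Accepted alignments are assigned to
#' overlapping target exons (reciprocal overlap of the aligned region with
#' the exon of at least half the shorter of the two), to a target intron
#' (aligned region inside the intron +/- `intron_slop` bp), or to nothing.
#'
#' @param geneA,geneB [gene_model()]s carrying genomic sequence.
#' @param min_identity Minimum alignment identity (default 0.6).
#' @param min_length Minimum aligned length in bp (default 30).
#' @param intron_slop Slop for the intron-containment test (default 10).
#' @return Object of class `exon_correspondence`: list with `AtoB` and
#'   `BtoA`, each a data.frame (one row per query exon) with alignment
#'   coordinates, `identity`, `hit_exons` (comma-joined indices),
#'   `hit_intron`, `assignment` in {"exon", "intron", "none"}.
#' @export
build_correspondence <- function(geneA, geneB, min_identity = 0.6,
                                 min_length = 30L, intron_slop = 10L) {
  one_side <- function(qry, tgt) {
    qex <- exon_seqs(qry)
    tex <- tgt$exons
    off <- gene_span(tgt)[1] - 1L
    tin <- introns(tgt)
    rows <- lapply(seq_along(qex), function(i) {
      al <- align_exon_to_gene(qex[i], tgt$genomic_seq)
      len <- al$end - al$start + 1L
      accepted <- al$aligned_length >= min_length && al$identity >= min_identity
      hit_exons <- integer(0); hit_intron <- NA_integer_
      assignment <- "none"
      if (accepted) {
        # aligned region in target span-local coords == subject coords
        a <- al$start; b <- al$end
        for (e in seq_len(nrow(tex))) {
          es <- tex[e, 1] - off; ee <- tex[e, 2] - off
          ov <- min(b, ee) - max(a, es) + 1L
          shorter <- min(b - a + 1L, ee - es + 1L)
          if (ov > 0 && ov >= 0.5 * shorter) hit_exons <- c(hit_exons, e)
        }
        if (length(hit_exons)) {
          assignment <- "exon"
        } else if (nrow(tin)) {
          for (e in seq_len(nrow(tin))) {
            is_ <- tin[e, 1] - off; ie_ <- tin[e, 2] - off
            if (a >= is_ - intron_slop && b <= ie_ + intron_slop) {
              hit_intron <- e
              assignment <- "intron"
              break
            }
          }
        }
      }
      data.frame(exon = i, accepted = accepted,
                 start = al$start, end = al$end, identity = al$identity,
                 aligned_length = al$aligned_length, score = al$score,
                 hit_exons = paste(hit_exons, collapse = ","),
                 hit_intron = hit_intron, assignment = assignment,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  structure(list(AtoB = one_side(geneA, geneB),
                 BtoA = one_side(geneB, geneA),
                 geneA_id = geneA$gene_id, geneB_id = geneB$gene_id),
            class = "exon_correspondence")
}

hits_of <- function(row) {
  if (row$assignment != "exon" || row$hit_exons == "") return(integer(0))
  as.integer(strsplit(row$hit_exons, ",")[[1]])
}

# 1-1 matched exon pairs (A exon i <-> B exon j), from reciprocal single hits
matched_pairs <- function(corr) {
  ab <- corr$AtoB; ba <- corr$BtoA
  out <- NULL
  for (i in seq_len(nrow(ab))) {
    h <- hits_of(ab[i, ])
    if (length(h) != 1) next
    back <- hits_of(ba[h, ])
    if (length(back) == 1 && back == i) out <- rbind(out, c(i, h))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("A", "B")
  out
}

#' Classify the divergence mechanisms of a paralog pair
#'
#' Applies the five mechanism rules in fixed priority order: exon split
#' (one exon corresponding to two adjacent exons of the sibling, the
#' intervening intron having no separate counterpart), exonization/
#' pseudoexonization (exon homolog inside a sibling intron), exon/intron
#' gain/loss (exon with no counterpart at all), exon/intron boundary
#' alteration (matched exon pair whose annotated lengths differ by at least
#' `min_offset` bp while the flanking introns stay within the elongation
#' factor), and intron elongation (a homologous intron - both flanking exon
#' pairs matched - whose length ratio exceeds `elongation_factor`). The
#' highest-priority event is the primary mechanism; all events are
#' reported. Event polarity (gain vs loss, exonization vs
#' pseudoexonization) is `"UNKNOWN"` without an outgroup.
#'
#' @param corr A [build_correspondence()] result.
#' @param geneA,geneB The gene models used to build it.
#' @param min_offset Minimum boundary offset in bp (default 3).
#' @param elongation_factor Intron length-ratio threshold (default 2).
#' @return Object of class `divergence_events`: list with `events`
#'   (data.frame `mechanism`, `feature_A`, `feature_B`, `detail`,
#'   `polarity`) and `primary` (mechanism string or `"NONE"`).
#' @export
classify_pair <- function(corr, geneA, geneB, min_offset = 3L,
                          elongation_factor = 2) {
  flA <- feature_lengths(geneA); flB <- feature_lengths(geneB)
  ev <- list()
  add <- function(mech, fa, fb, detail) {
    ev[[length(ev) + 1L]] <<- data.frame(
      mechanism = mech, feature_A = fa, feature_B = fb, detail = detail,
      polarity = "UNKNOWN", stringsAsFactors = FALSE)
  }
  explainedA <- integer(0); explainedB <- integer(0)

  # --- exon split: one query exon covering >= 2 adjacent target exons
  for (i in seq_len(nrow(corr$AtoB))) {
    h <- hits_of(corr$AtoB[i, ])
    if (length(h) >= 2 && all(diff(sort(h)) == 1)) {
      add("EXON_SPLIT", paste0("exon", i),
          paste0("exon", paste(sort(h), collapse = "+")),
          sprintf("A exon %d spans B exons %s", i, paste(sort(h), collapse = ",")))
      explainedA <- c(explainedA, i); explainedB <- c(explainedB, h)
    }
  }
  for (j in seq_len(nrow(corr$BtoA))) {
    h <- hits_of(corr$BtoA[j, ])
    if (length(h) >= 2 && all(diff(sort(h)) == 1)) {
      add("EXON_SPLIT", paste0("exon", paste(sort(h), collapse = "+")),
          paste0("exon", j),
          sprintf("B exon %d spans A exons %s", j, paste(sort(h), collapse = ",")))
      explainedB <- c(explainedB, j); explainedA <- c(explainedA, h)
    }
  }
  # two adjacent target exons mapping into one query exon (split seen from
  # the other side when the alignment does not bridge the novel intron)
  split_from_pieces <- function(side, qn) {
    tab <- if (side == "B") corr$BtoA else corr$AtoB
    for (j in seq_len(nrow(tab) - 1L)) {
      h1 <- hits_of(tab[j, ]); h2 <- hits_of(tab[j + 1L, ])
      common <- intersect(h1, h2)
      if (length(common) == 1) {
        if (side == "B") {
          if (j %in% explainedB || (j + 1L) %in% explainedB) next
          add("EXON_SPLIT", paste0("exon", common),
              paste0("exon", j, "+", j + 1L),
              sprintf("B exons %d,%d tile A exon %d", j, j + 1L, common))
          explainedB <<- c(explainedB, j, j + 1L)
          explainedA <<- c(explainedA, common)
        } else {
          if (j %in% explainedA || (j + 1L) %in% explainedA) next
          add("EXON_SPLIT", paste0("exon", j, "+", j + 1L),
              paste0("exon", common),
              sprintf("A exons %d,%d tile B exon %d", j, j + 1L, common))
          explainedA <<- c(explainedA, j, j + 1L)
          explainedB <<- c(explainedB, common)
        }
      }
    }
  }
  split_from_pieces("B")
  split_from_pieces("A")

  # --- exonization / pseudoexonization: exon homolog inside an intron
  for (i in seq_len(nrow(corr$AtoB))) {
    r <- corr$AtoB[i, ]
    if (r$assignment == "intron" && !(i %in% explainedA)) {
      add("EXONIZATION_PSEUDOEXONIZATION", paste0("exon", i),
          paste0("intron", r$hit_intron),
          sprintf("A exon %d homolog lies in B intron %d (id %.2f)",
                  i, r$hit_intron, r$identity))
      explainedA <- c(explainedA, i)
    }
  }
  for (j in seq_len(nrow(corr$BtoA))) {
    r <- corr$BtoA[j, ]
    if (r$assignment == "intron" && !(j %in% explainedB)) {
      add("EXONIZATION_PSEUDOEXONIZATION", paste0("intron", r$hit_intron),
          paste0("exon", j),
          sprintf("B exon %d homolog lies in A intron %d (id %.2f)",
                  j, r$hit_intron, r$identity))
      explainedB <- c(explainedB, j)
    }
  }

  # --- exon/intron gain/loss: exon with no counterpart
  for (i in seq_len(nrow(corr$AtoB))) {
    if (corr$AtoB[i, ]$assignment == "none" && !(i %in% explainedA)) {
      add("EXON_INTRON_GAIN_LOSS", paste0("exon", i), "none",
          sprintf("A exon %d (%d bp) has no counterpart in B", i, flA$exon[i]))
      explainedA <- c(explainedA, i)
    }
  }
  for (j in seq_len(nrow(corr$BtoA))) {
    if (corr$BtoA[j, ]$assignment == "none" && !(j %in% explainedB)) {
      add("EXON_INTRON_GAIN_LOSS", "none", paste0("exon", j),
          sprintf("B exon %d (%d bp) has no counterpart in A", j, flB$exon[j]))
      explainedB <- c(explainedB, j)
    }
  }

  mp <- matched_pairs(corr)
  if (nrow(mp)) {
    mp <- mp[!(mp[, 1] %in% explainedA) & !(mp[, 2] %in% explainedB), ,
             drop = FALSE]
  }

  # --- boundary alteration: matched exons with different annotated lengths
  for (k in seq_len(nrow(mp))) {
    i <- mp[k, 1]; j <- mp[k, 2]
    d <- abs(flA$exon[i] - flB$exon[j])
    if (d >= min_offset) {
      # flanking introns must not themselves be grossly elongated
      ratios <- c()
      if (i > 1 && j > 1) ratios <- c(ratios,
        max(flA$intron[i - 1], flB$intron[j - 1]) /
        min(flA$intron[i - 1], flB$intron[j - 1]))
      if (i <= length(flA$intron) && j <= length(flB$intron)) ratios <- c(ratios,
        max(flA$intron[i], flB$intron[j]) / min(flA$intron[i], flB$intron[j]))
      if (!length(ratios) || all(ratios <= elongation_factor)) {
        add("BOUNDARY_ALTERATION", paste0("exon", i), paste0("exon", j),
            sprintf("matched exons differ by %d bp (A %d, B %d)",
                    d, flA$exon[i], flB$exon[j]))
      }
    }
  }

  # --- intron elongation: homologous intron (both flanks matched) ratio > 2
  if (nrow(mp) >= 2) {
    mp <- mp[order(mp[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(mp) - 1L)) {
      i <- mp[k, 1]; j <- mp[k, 2]
      if (mp[k + 1L, 1] == i + 1L && mp[k + 1L, 2] == j + 1L) {
        la <- flA$intron[i]; lb <- flB$intron[j]
        ratio <- max(la, lb) / min(la, lb)
        if (ratio > elongation_factor) {
          add("INTRON_ELONGATION", paste0("intron", i), paste0("intron", j),
              sprintf("homologous intron lengths %d vs %d (ratio %.2f)",
                      la, lb, ratio))
        }
      }
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(mechanism = character(0), feature_A = character(0),
               feature_B = character(0), detail = character(0),
               polarity = character(0))
  prio <- c("EXON_SPLIT", "EXONIZATION_PSEUDOEXONIZATION",
            "EXON_INTRON_GAIN_LOSS", "BOUNDARY_ALTERATION",
            "INTRON_ELONGATION")
  primary <- if (nrow(events)) prio[min(match(events$mechanism, prio))] else "NONE"
  structure(list(events = events, primary = primary),
            class = "divergence_events")
}

#' @export
print.divergence_events <- function(x, ...) {
  cat(sprintf("<divergence_events> primary: %s (%d event(s))\n",
              x$primary, nrow(x$events)))
  if (nrow(x$events)) print(x$events[, c("mechanism", "feature_A", "feature_B")])
  invisible(x)
}

#' Structured comparison record for a classified pair
#'
#' @param dv A [classify_pair()] result.
#' @param geneA,geneB The compared gene models.
#' @return List with per-gene feature lengths, the event table, a mechanism
#'   tally (named integer vector over the five mechanisms), and the primary
#'   mechanism.
#' @export
pair_report <- function(dv, geneA, geneB) {
  mechs <- c("EXON_SPLIT", "EXONIZATION_PSEUDOEXONIZATION",
             "EXON_INTRON_GAIN_LOSS", "BOUNDARY_ALTERATION",
             "INTRON_ELONGATION")
  tally <- stats::setNames(integer(length(mechs)), mechs)
  if (nrow(dv$events)) {
    tb <- table(dv$events$mechanism)
    tally[names(tb)] <- as.integer(tb)
  }
  list(geneA = geneA$gene_id, geneB = geneB$gene_id,
       lengths_A = feature_lengths(geneA), lengths_B = feature_lengths(geneB),
       events = dv$events, mechanism_tally = tally, primary = dv$primary)
}
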