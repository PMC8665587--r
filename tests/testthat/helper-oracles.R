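# Independent brute-force oracles used to validate the implementation.
# Each is written as a naive re-derivation from first principles and shares
# no code with the package internals it checks.

CODE <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

## ---- NG86 oracle -----------------------------------------------------------

oracle_codon_sites <- function(codon) {
  aa <- CODE[[codon]]
  s_total <- 0
  for (pos in 1:3) {
    syn <- 0; counted <- 0
    for (b in BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (CODE[[mut]] == "*") next
      counted <- counted + 1
      if (CODE[[mut]] == aa) syn <- syn + 1
    }
    if (counted > 0) s_total <- s_total + syn / counted
  }
  c(s_total, 3 - s_total)
}

# all orderings of the differing positions, via recursive enumeration
oracle_perms <- function(x) {
  if (length(x) <= 1) return(matrix(x, nrow = 1))
  do.call(rbind, lapply(seq_along(x), function(i)
    cbind(x[i], oracle_perms(x[-i]))))
}

oracle_codon_diffs <- function(ca, cb) {
  dp <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(dp)) return(c(0, 0))
  pm <- oracle_perms(dp)
  res <- matrix(NA_real_, nrow(pm), 2)
  ok <- logical(nrow(pm))
  for (r in seq_len(nrow(pm))) {
    cur <- ca; sd <- 0; nd <- 0; hit_stop <- FALSE
    for (pos in pm[r, ]) {
      nxt <- paste0(substr(cur, 1, pos - 1), substr(cb, pos, pos),
                    substr(cur, pos + 1, 3))
      if (CODE[[nxt]] == "*") hit_stop <- TRUE
      else if (CODE[[nxt]] == CODE[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[r, ] <- c(sd, nd)
    ok[r] <- !hit_stop
  }
  if (!any(ok)) ok[] <- TRUE
  colMeans(res[ok, , drop = FALSE])
}

oracle_ng86 <- function(cdsA, cdsB) {
  n <- nchar(cdsA) / 3
  ca <- substring(cdsA, 3 * (1:n) - 2, 3 * (1:n))
  cb <- substring(cdsB, 3 * (1:n) - 2, 3 * (1:n))
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  keep <- keep & vapply(ca, function(x) CODE[[x]] != "*", logical(1)) &
    vapply(cb, function(x) CODE[[x]] != "*", logical(1))
  ca <- ca[keep]; cb <- cb[keep]
  SA <- sum(vapply(ca, function(x) oracle_codon_sites(x)[1], numeric(1)))
  SB <- sum(vapply(cb, function(x) oracle_codon_sites(x)[1], numeric(1)))
  d <- vapply(seq_along(ca), function(i) oracle_codon_diffs(ca[i], cb[i]),
              numeric(2))
  S <- (SA + SB) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p < 0.75) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

random_sense_cds <- function(n_codons) {
  sense <- names(CODE)[CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

## ---- Smith-Waterman affine-gap DP oracle (Gotoh) ---------------------------
## gap of length L costs open + L * ext (matches the package convention)

oracle_sw_score <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (va[i] == vb[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

## ---- tandem clustering oracle: O(n^2) pairwise links + union-find ----------

oracle_tandem <- function(ranks_by_chrom, max_gap) {
  # ranks_by_chrom: named list chrom -> integer ranks of family genes
  comp <- list()
  for (ch in names(ranks_by_chrom)) {
    r <- ranks_by_chrom[[ch]]
    n <- length(r)
    parent <- seq_len(n)
    findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && abs(r[i] - r[j]) <= max_gap + 1) {
        pi <- findp(i); pj <- findp(j)
        if (pi != pj) parent[pj] <- pi
      }
    }
    roots <- vapply(seq_len(n), findp, integer(1))
    comp[[ch]] <- split(r, roots)
  }
  comp
}

## ---- dot matrix oracle: naive double loop ----------------------------------

oracle_dot_matches <- function(seq, window = 30, min_identity = 0.6) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  need <- ceiling(window * min_identity)
  out <- NULL
  for (i in seq_len(L - window + 1)) {
    for (j in seq_len(L - window + 1)) {
      if (j <= i) next
      nm <- sum(v[i:(i + window - 1)] == v[j:(j + window - 1)])
      if (nm >= need) out <- rbind(out, c(i, j, nm))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 3)
  colnames(out) <- c("i", "j", "n_match")
  out
}

## ---- duplication-loss reconciliation oracle --------------------------------
## minimum DL cost over all valid gene->species node mappings, by
## exhaustive enumeration (small trees only)

oracle_species_index <- function(sphy) {
  ntip <- ape::Ntip(sphy)
  nn <- ntip + sphy$Nnode
  parent <- integer(nn)
  parent[sphy$edge[, 2]] <- sphy$edge[, 1]
  root <- setdiff(sphy$edge[, 1], sphy$edge[, 2])[1]
  anc <- vector("list", nn)  # ancestors-or-self, node -> root path
  for (v in seq_len(nn)) {
    path <- v
    x <- v
    while (x != root) { x <- parent[x]; path <- c(path, x) }
    anc[[v]] <- path
  }
  dist <- matrix(NA_integer_, nn, nn)  # edges between comparable nodes
  for (v in seq_len(nn)) {
    dist[v, anc[[v]]] <- seq_along(anc[[v]]) - 1L
    dist[anc[[v]], v] <- seq_along(anc[[v]]) - 1L
  }
  list(ntip = ntip, nn = nn, parent = parent, root = root, anc = anc,
       dist = dist)
}

oracle_dl_cost <- function(gphy, sphy, species_of) {
  si <- oracle_species_index(sphy)
  gt_ntip <- ape::Ntip(gphy)
  gt_nn <- gt_ntip + gphy$Nnode
  gparent <- integer(gt_nn)
  gparent[gphy$edge[, 2]] <- gphy$edge[, 1]
  groot <- setdiff(gphy$edge[, 1], gphy$edge[, 2])[1]
  gchildren <- vector("list", gt_nn)
  for (e in seq_len(nrow(gphy$edge))) {
    p <- gphy$edge[e, 1]
    gchildren[[p]] <- c(gchildren[[p]], gphy$edge[e, 2])
  }
  leaf_map <- match(species_of[gphy$tip.label], sphy$tip.label)
  internals <- setdiff(seq_len(gt_nn), seq_len(gt_ntip))
  # candidates: ancestors-or-self of the species LCA of each subtree's leaves
  sp_lca <- function(nodes) {
    common <- Reduce(intersect, si$anc[nodes])
    common[1]  # paths are ordered node -> root; first common = LCA
  }
  clade_leaves <- function(v) {
    if (v <= gt_ntip) return(v)
    unlist(lapply(gchildren[[v]], clade_leaves))
  }
  cand <- lapply(internals, function(v)
    si$anc[[sp_lca(leaf_map[clade_leaves(v)])]])
  grid <- do.call(expand.grid, cand)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    M <- integer(gt_nn)
    M[seq_len(gt_ntip)] <- leaf_map
    M[internals] <- as.integer(grid[r, ])
    valid <- TRUE
    ndup <- 0L; nloss <- 0L
    for (v in internals) {
      ch <- gchildren[[v]]
      # children must map within the subtree of M(v)
      if (!(M[v] %in% si$anc[[M[ch[1]]]]) || !(M[v] %in% si$anc[[M[ch[2]]]])) {
        valid <- FALSE; break
      }
      is_spec <- M[v] == sp_lca(M[ch]) && M[ch[1]] != M[v] && M[ch[2]] != M[v]
      if (!is_spec) ndup <- ndup + 1L
    }
    if (!valid) next
    dup_flag <- logical(gt_nn)
    for (v in internals) {
      ch <- gchildren[[v]]
      dup_flag[v] <- !(M[v] == sp_lca(M[ch]) && M[ch[1]] != M[v] && M[ch[2]] != M[v])
    }
    for (e in seq_len(nrow(gphy$edge))) {
      u <- gphy$edge[e, 1]; v <- gphy$edge[e, 2]
      d <- si$dist[M[u], M[v]]
      nloss <- nloss + if (dup_flag[u]) d else max(d - 1L, 0L)
    }
    best <- min(best, ndup + nloss)
  }
  best
}

# all rooted binary topologies (as Newick strings without the trailing ";")
# over the given leaf labels
all_topologies <- function(labels) {
  n <- length(labels)
  if (n == 1) return(labels)
  out <- character(0)
  # split: subsets containing labels[1] to avoid mirror duplicates
  rest <- labels[-1]
  for (k in 0:(length(rest) - 1)) {
    combs <- utils::combn(rest, k, simplify = FALSE)
    for (cmb in combs) {
      left <- c(labels[1], cmb)
      right <- setdiff(labels, left)
      for (l in all_topologies(left)) for (r in all_topologies(right)) {
        out <- c(out, paste0("(", l, ",", r, ")"))
      }
    }
  }
  out
}

# map simulator mechanism names onto classifier event names
classifier_label <- function(sim_mechanism) {
  switch(sim_mechanism,
         BOUNDARY_SHIFT = "BOUNDARY_ALTERATION",
         EXONIZATION = "EXONIZATION_PSEUDOEXONIZATION",
         sim_mechanism)
}
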