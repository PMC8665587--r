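## Duplication-loss maximum-parsimony reconciliation of gene trees against
## a species tree (LCA mapping), aggregated into per-branch gains/losses and
## ancestral family sizes.

as_phylo_tree <- function(x) {
  if (inherits(x, "labeled_tree")) x$tree else x
}

# Index a rooted phylo: parents, children, depths, per-node labels.
tree_index <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  children <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    children[[p]] <- c(children[[p]], phy$edge[e, 2])
  }
  depth <- integer(nn)
  ord <- root
  while (length(ord)) {
    nxt <- integer(0)
    for (v in ord) for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      nxt <- c(nxt, c)
    }
    ord <- nxt
  }
  lab <- character(nn)
  lab[seq_len(ntip)] <- phy$tip.label
  # internal labels: sorted tip labels of the clade, joined (postorder so
  # children's tip sets exist before their parent needs them)
  po <- postorder_nodes(phy, root, children)
  for (v in po) if (v > ntip) {
    tips <- unlist(lapply(children[[v]], function(c)
      if (c <= ntip) phy$tip.label[c] else attr(lab, "tipsets")[[c]]))
    ts <- attr(lab, "tipsets") %||% vector("list", nn)
    ts[[v]] <- sort(tips)
    attr(lab, "tipsets") <- ts
    lab[v] <- paste(sort(tips), collapse = "+")
  }
  list(ntip = ntip, n_nodes = nn, parent = parent, children = children,
       root = root, depth = depth, label = as.character(lab))
}

postorder_nodes <- function(phy, root, children) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(v, out)
    stack <- c(stack, children[[v]])
  }
  out
}

# LCA of two nodes given parent/depth arrays.
node_lca <- function(a, b, idx) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a] else b <- idx$parent[b]
  }
  a
}

#' LCA duplication-loss parsimony reconciliation
#'
#' Maps every gene-tree node to the species-tree LCA of its leaf species,
#' labels internal gene nodes as speciation or duplication, and counts the
#' implied losses per species branch. Under unit event costs the LCA mapping
#' attains the minimum duplication + loss cost.
#'
#' @param gene_tree A [read_newick()] result (or `phylo`) whose leaves carry
#'   a species mapping, either via the `labeled_tree` `species_of` field or
#'   `species_map`.
#' @param species_tree Rooted binary species tree (`labeled_tree` or
#'   `phylo`) with unique tip labels.
#' @param species_map Optional named vector gene leaf -> species.
#' @return Object of class `reconciliation`: list with `lca_map` (species
#'   node index per gene node), `events` (named character, internal gene
#'   nodes: `"DUPLICATION"`/`"SPECIATION"`), `dup_at` (species node label of
#'   each duplication), `losses` (data.frame `branch` = label of the species
#'   node the lost branch enters, `count`), `n_dup`, `n_loss`, `cost`,
#'   `root_species` (label), and `species_index`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, species_map = NULL) {
  gphy <- as_phylo_tree(gene_tree)
  sphy <- as_phylo_tree(species_tree)
  if (!ape::is.binary(gphy) || !ape::is.binary(sphy)) {
    stop("gene and species trees must be binary (resolve polytomies first)")
  }
  species_of <- species_map
  if (inherits(gene_tree, "labeled_tree") && is.null(species_of)) {
    species_of <- gene_tree$species_of
  }
  if (is.null(species_of)) stop("no gene -> species mapping available")
  sidx <- tree_index(sphy)
  gidx <- tree_index(gphy)
  leaf_sp <- species_of[gphy$tip.label]
  if (anyNA(leaf_sp)) {
    stop("unmapped gene leaves: ",
         paste(gphy$tip.label[is.na(leaf_sp)], collapse = ", "))
  }
  sp_node <- match(leaf_sp, sphy$tip.label)
  if (anyNA(sp_node)) {
    stop("species not in species tree: ",
         paste(unique(leaf_sp[is.na(sp_node)]), collapse = ", "))
  }
  nn <- gidx$n_nodes
  lca_map <- integer(nn)
  lca_map[seq_len(gidx$ntip)] <- sp_node
  events <- character(nn)
  po <- postorder_nodes(gphy, gidx$root, gidx$children)
  for (v in po) {
    if (v <= gidx$ntip) next
    ch <- gidx$children[[v]]
    m <- node_lca(lca_map[ch[1]], lca_map[ch[2]], sidx)
    lca_map[v] <- m
    events[v] <- if (m == lca_map[ch[1]] || m == lca_map[ch[2]])
      "DUPLICATION" else "SPECIATION"
  }
  # losses per gene edge, attributed to the species branch they occur on
  loss_at <- integer(0)  # species node ids whose entering branch lost a copy
  for (e in seq_len(nrow(gphy$edge))) {
    u <- gphy$edge[e, 1]; v <- gphy$edge[e, 2]
    a <- lca_map[u]; b <- lca_map[v]
    if (a == b) next
    # path b -> a (exclusive of a); siblings along it are lost
    path <- b
    x <- b
    while (sidx$parent[x] != a) {
      x <- sidx$parent[x]
      path <- c(path, x)
    }
    # path = p_k (=b), ..., p_1 (child of a), top to bottom reversed
    sib_of <- function(node) {
      ch <- sidx$children[[sidx$parent[node]]]
      ch[ch != node]
    }
    if (events[u] == "DUPLICATION") {
      # lineage starts at a itself: off-path child of a is lost too
      loss_at <- c(loss_at, vapply(path, sib_of, integer(1)))
    } else if (length(path) > 1) {
      loss_at <- c(loss_at, vapply(path[-length(path)], sib_of, integer(1)))
    }
  }
  dup_nodes <- which(events == "DUPLICATION")
  n_dup <- length(dup_nodes)
  n_loss <- length(loss_at)
  losses <- if (n_loss) {
    tb <- table(sidx$label[loss_at])
    data.frame(branch = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  } else data.frame(branch = character(0), count = integer(0))
  structure(list(lca_map = lca_map,
                 events = stats::setNames(events[events != ""],
                                          gidx$label[which(events != "")]),
                 event_nodes = which(events != ""),
                 event_labels = events[events != ""],
                 dup_at = sidx$label[lca_map[dup_nodes]],
                 loss_at = sidx$label[loss_at],
                 losses = losses,
                 n_dup = n_dup, n_loss = n_loss, cost = n_dup + n_loss,
                 root_species = sidx$label[lca_map[gidx$root]],
                 species_index = sidx),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> %d duplication(s), %d loss(es), cost %d; root maps to %s\n",
              x$n_dup, x$n_loss, x$cost, x$root_species))
  invisible(x)
}

#' Aggregate reconciliations into a per-branch family history
#'
#' Sums duplications (gains) and losses per species branch over a forest of
#' reconciled gene families and computes ancestral copy numbers top-down so
#' that `count(child) = count(parent) + gains - losses` holds on every
#' branch. Each family contributes one origin gain on the branch entering
#' the species LCA of its observed species (no phantom losses above a
#' family's root).
#'
#' @param recons List of [lca_reconcile()] results over the same species tree.
#' @param species_tree The species tree used.
#' @param observed_counts Optional named vector species -> observed family
#'   size; checked against the forest's leaf counts.
#' @return Object of class `family_history`: data.frame with one row per
#'   species-tree node: `node`, `parent`, `is_tip`, `gains`, `origin_gains`,
#'   `losses`, `count`.
#' @export
aggregate_histories <- function(recons, species_tree, observed_counts = NULL) {
  sphy <- as_phylo_tree(species_tree)
  sidx <- tree_index(sphy)
  nn <- sidx$n_nodes
  gains <- integer(nn); losses <- integer(nn); origins <- integer(nn)
  leaf_counts <- stats::setNames(integer(sidx$ntip), sidx$label[seq_len(sidx$ntip)])
  for (rc in recons) {
    if (!inherits(rc, "reconciliation")) stop("not a reconciliation object")
    di <- match(rc$dup_at, sidx$label)
    li <- match(rc$loss_at, sidx$label)
    ri <- match(rc$root_species, sidx$label)
    if (anyNA(c(di, li, ri))) stop("reconciliation uses a different species tree")
    for (i in di) gains[i] <- gains[i] + 1L
    for (i in li) losses[i] <- losses[i] + 1L
    origins[ri] <- origins[ri] + 1L
    # leaf species of this family's gene tree (ape tips are nodes 1..ntip)
    ntip_g <- length(rc$lca_map) - length(rc$event_nodes)
    gl <- rc$species_index$label[rc$lca_map[seq_len(ntip_g)]]
    tb <- table(gl)
    for (s in names(tb)) leaf_counts[s] <- leaf_counts[s] + tb[[s]]
  }
  if (!is.null(observed_counts)) {
    cmp <- observed_counts[names(leaf_counts)]
    if (any(is.na(cmp)) || any(cmp != leaf_counts)) {
      stop("observed counts inconsistent with the reconciled forest")
    }
  }
  count <- integer(nn)
  pre <- rev(postorder_nodes(sphy, sidx$root, sidx$children))
  for (v in pre) {
    pc <- if (v == sidx$root) 0L else count[sidx$parent[v]]
    count[v] <- pc + origins[v] + gains[v] - losses[v]
  }
  par_lab <- rep(NA_character_, nn)
  nonroot <- seq_len(nn) != sidx$root
  par_lab[nonroot] <- sidx$label[sidx$parent[nonroot]]
  out <- data.frame(
    node = sidx$label,
    parent = par_lab,
    is_tip = seq_len(nn) <= sidx$ntip,
    gains = gains, origin_gains = origins, losses = losses, count = count,
    stringsAsFactors = FALSE)
  structure(out, class = c("family_history", "data.frame"))
}
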