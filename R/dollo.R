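#' Read a family presence/absence matrix
#'
#' @param path TSV with families as rows (first column `family_id`,
#'   optional `rna_class` column) and one 0/1 column per taxon.
#' @return List of class `presence_matrix`: `matrix` (families x taxa,
#'   0/1), `class_of` (named vector).
#' @export
read_presence_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  make_presence_matrix(df)
}

#' Construct a presence/absence matrix object
#'
#' @param df Data.frame with `family_id`, optional `rna_class`, then one
#'   binary column per taxon.
#' @return A `presence_matrix`.
#' @export
make_presence_matrix <- function(df) {
  stopifnot("family_id" %in% names(df))
  class_of <- if ("rna_class" %in% names(df))
    setNames(df$rna_class, df$family_id) else
    setNames(rep(NA_character_, nrow(df)), df$family_id)
  taxa <- setdiff(names(df), c("family_id", "rna_class"))
  m <- as.matrix(df[, taxa, drop = FALSE])
  rownames(m) <- df$family_id
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("presence matrix cells must be 0/1")
  structure(list(matrix = m, class_of = class_of), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence/absence matrix: ", nrow(x$matrix), " families x ",
      ncol(x$matrix), " taxa\n", sep = "")
  invisible(x)
}

# --- small rooted-tree helpers on an ape "phylo" object ---

tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  ch
}

tree_parent <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

node_labels <- function(tree) {
  c(tree$tip.label,
    if (!is.null(tree$node.label)) tree$node.label else
      paste0("node", seq_len(tree$Nnode) + ape::Ntip(tree)))
}

# tips under each node (list over all node ids)
tips_under <- function(tree) {
  ntip <- ape::Ntip(tree)
  ch <- tree_children(tree)
  n_nodes <- ntip + tree$Nnode
  out <- vector("list", n_nodes)
  # postorder over internal nodes
  ord <- rev(unique(tree$edge[, 1][order(tree$edge[, 1])]))
  for (i in seq_len(ntip)) out[[i]] <- i
  done <- rep(FALSE, n_nodes)
  done[seq_len(ntip)] <- TRUE
  repeat {
    progressed <- FALSE
    for (v in (ntip + 1):n_nodes) {
      if (done[v]) next
      if (all(done[ch[[v]]])) {
        out[[v]] <- sort(unlist(out[ch[[v]]]))
        done[v] <- TRUE
        progressed <- TRUE
      }
    }
    if (all(done)) break
    if (!progressed) stop("malformed tree")
  }
  out
}

ancestors_of <- function(tree, v) {
  par <- tree_parent(tree)
  out <- integer(0)
  while (!is.na(par[v])) { v <- par[v]; out <- c(out, v) }
  out
}

mrca_of <- function(tree, nodes) {
  if (length(nodes) == 1) return(nodes)
  paths <- lapply(nodes, function(v) c(v, ancestors_of(tree, v)))
  common <- Reduce(intersect, paths)
  common[1]  # paths list ancestors bottom-up; first common is the MRCA
}

#' Dollo-parsimony reconstruction of family histories on a rooted tree
#'
#' Under Dollo parsimony each family is gained exactly once and may be
#' lost repeatedly.  The gain is placed at the most recent common
#' ancestor of all presence leaves; a node is present iff it lies on a
#' path from the gain node to a presence leaf.  Hard constraints
#' (published ancestral states) override parsimony placement: a
#' presence constraint above the gain relocates the gain to cover it; a
#' constrained-present node off the presence paths stays present (its
#' descendants absent unless on a path), adding loss events on its
#' child edges.  An absence constraint contradicting an observed leaf
#' or a required path is an error.
#'
#' @param tree Rooted `phylo` tree (leaf names must match the matrix
#'   taxa; internal node labels are used in reports).
#' @param pm A `presence_matrix` (or plain families x taxa 0/1 matrix).
#' @param constraints Optional data.frame with columns `node` (label),
#'   `family_id`, `state` (0/1).
#' @return List of class `dollo_reconstruction`: `states` (families x
#'   nodes 0/1 matrix, columns named by node labels), `gain_node` (named
#'   vector), `loss_edges` (list of child-node labels per family),
#'   `tree`, plus the per-edge/per-node aggregates of
#'   [edge_and_node_summary()].
#' @export
dollo_reconstruct <- function(tree, pm, constraints = NULL) {
  m <- if (inherits(pm, "presence_matrix")) pm$matrix else pm
  ntip <- ape::Ntip(tree)
  if (!setequal(colnames(m), tree$tip.label))
    stop("matrix taxa do not match tree leaves")
  m <- m[, tree$tip.label, drop = FALSE]
  labels <- node_labels(tree)
  n_nodes <- ntip + tree$Nnode
  par <- tree_parent(tree)
  tu <- tips_under(tree)
  states <- matrix(0L, nrow(m), n_nodes,
                   dimnames = list(rownames(m), labels))
  gain_node <- setNames(rep(NA_character_, nrow(m)), rownames(m))
  loss_edges <- setNames(vector("list", nrow(m)), rownames(m))
  cons <- constraints
  if (!is.null(cons)) {
    stopifnot(all(c("node", "family_id", "state") %in% names(cons)))
    bad <- !cons$node %in% labels
    if (any(bad)) stop("constraint on unknown node: ", cons$node[bad][1])
  }
  for (f in seq_len(nrow(m))) {
    fam <- rownames(m)[f]
    pres_tips <- which(m[f, ] == 1L)
    fcons <- if (!is.null(cons)) cons[cons$family_id == fam, , drop = FALSE] else NULL
    forced_present <- forced_absent <- integer(0)
    if (!is.null(fcons) && nrow(fcons)) {
      ids <- match(fcons$node, labels)
      leafc <- ids <= ntip
      # constraints on leaves must agree with the matrix
      if (any(leafc)) {
        obs <- m[f, ids[leafc]]
        if (any(obs != fcons$state[leafc]))
          stop("constraint contradicts leaf observation for family ", fam)
      }
      forced_present <- ids[fcons$state == 1L]
      forced_absent <- ids[fcons$state == 0L]
    }
    anchor <- c(pres_tips, forced_present)
    if (!length(anchor)) next  # family absent everywhere
    gain <- mrca_of(tree, unique(anchor))
    # present = nodes on a path from gain to an anchor
    present <- unique(unlist(lapply(unique(anchor), function(v) {
      path <- c(v, ancestors_of(tree, v))
      path[seq_len(match(gain, path))]
    })))
    if (length(conflict <- intersect(forced_absent, present)))
      stop("absence constraint at '", labels[conflict[1]],
           "' contradicts required presence for family ", fam)
    states[f, present] <- 1L
    gain_node[f] <- labels[gain]
    # losses: edges parent-present -> child-absent
    child_nodes <- tree$edge[, 2]
    lost <- child_nodes[states[f, tree$edge[, 1]] == 1L &
                          states[f, child_nodes] == 0L]
    loss_edges[[f]] <- labels[lost]
  }
  recon <- structure(list(states = states, gain_node = gain_node,
                          loss_edges = loss_edges, tree = tree),
                     class = "dollo_reconstruction")
  recon$summary <- edge_and_node_summary(recon)
  recon
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("Dollo reconstruction: ", nrow(x$states), " families on ",
      ncol(x$states), " nodes\n", sep = "")
  invisible(x)
}

#' Per-node family counts and per-edge gain/loss aggregates
#'
#' Satisfies the bookkeeping identity
#' `count(child) = count(parent) + gains(edge) - losses(edge)` on every
#' edge (see [propagate_count()]).
#'
#' @param recon A [dollo_reconstruct()] result.
#' @return List with `node_counts` (named vector) and `edges`
#'   (data.frame: `parent`, `child`, `gains`, `losses`,
#'   `parent_count`, `child_count`).
#' @export
edge_and_node_summary <- function(recon) {
  tree <- recon$tree
  labels <- node_labels(tree)
  counts <- colSums(recon$states)
  gains_by_node <- table(factor(recon$gain_node, levels = labels))
  edges <- data.frame(
    parent = labels[tree$edge[, 1]],
    child = labels[tree$edge[, 2]],
    stringsAsFactors = FALSE)
  edges$gains <- as.integer(gains_by_node[edges$child])
  edges$losses <- vapply(edges$child, function(ch) {
    sum(vapply(recon$loss_edges, function(l) ch %in% l, TRUE))
  }, 0L)
  edges$parent_count <- as.integer(counts[edges$parent])
  edges$child_count <- as.integer(counts[edges$child])
  list(node_counts = counts, edges = edges)
}

#' Propagate a family count along edges with gain/loss events
#'
#' The elementary Dollo bookkeeping step: applying `gains` and `losses`
#' successively to an ancestral count gives the descendant count,
#' `count + cumsum(gains - losses)`.
#'
#' @param count Ancestral family count.
#' @param gains,losses Integer vectors of per-edge events, ordered from
#'   the ancestor outward.
#' @return Vector of counts after each edge.
#' @export
propagate_count <- function(count, gains, losses) {
  stopifnot(length(gains) == length(losses))
  count + cumsum(gains - losses)
}

#' Shared and group-specific family sets
#'
#' @param pm `presence_matrix` (or 0/1 matrix).
#' @param group_a,group_b Disjoint character vectors of taxa.
#' @return List with `shared`, `a_specific`, `b_specific` family id
#'   vectors: a family is `a_specific` when present in at least one
#'   member of A and no member of B (symmetrically for B), `shared` when
#'   present in at least one member of each.
#' @export
family_sets <- function(pm, group_a, group_b) {
  m <- if (inherits(pm, "presence_matrix")) pm$matrix else pm
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  stopifnot(all(c(group_a, group_b) %in% colnames(m)))
  in_a <- rowSums(m[, group_a, drop = FALSE]) > 0
  in_b <- rowSums(m[, group_b, drop = FALSE]) > 0
  list(shared = rownames(m)[in_a & in_b],
       a_specific = rownames(m)[in_a & !in_b],
       b_specific = rownames(m)[!in_a & in_b])
}

#' The default chordate species tree fixture
#'
#' A rooted tree over the 12 study taxa (tunicates, cephalochordate,
#' vertebrates, and a protostome outgroup) with named internal nodes
#' (Bilateria, Chordata, Olfactores, Tunicata, Craniata, ...).  Shipped
#' as an editable Newick file under `extdata`.
#'
#' @return An `ape::phylo` tree.
#' @export
default_species_tree <- function() {
  ape::read.tree(system.file("extdata", "species_tree.nwk",
                             package = "rnahomology"))
}
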