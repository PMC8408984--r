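# Gene-clade complements on a taxonomy: presence matrices and Dollo
# parsimony reconstruction of gains and losses.
#
# Dollo parsimony: each gene clade is gained exactly once (on the branch
# above the most recent common ancestor of all lineages possessing it) and
# may subsequently be lost any number of times; losses are placed on the
# minimal set of branches pruning every non-possessing descendant. Placing
# one loss on each maximal subtree devoid of possessing lineages attains the
# minimum, and that placement is unique, so no tie-breaking arises.

#' Build a taxa x clade presence (count) matrix
#'
#' @param partition A `clade_partition`.
#' @return Integer matrix of class `presence_matrix`: rows taxa, columns
#'   clades, entries sequence counts (presence = count > 0). Row/column
#'   order follows first appearance in the partition; all-zero columns are
#'   retained.
#' @export
presence_matrix <- function(partition) {
  taxa <- unique(partition$taxon)
  clades <- unique(partition$clade)
  m <- table(factor(partition$taxon, levels = taxa),
             factor(partition$clade, levels = clades))
  m <- matrix(as.integer(m), nrow = length(taxa),
              dimnames = list(taxa, clades))
  structure(m, class = c("presence_matrix", "matrix"))
}

#' Read a presence matrix from TSV
#'
#' Wide format: header `taxon` then one column per clade; integer counts.
#'
#' @param path Path to the TSV file.
#' @return A `presence_matrix`.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon") {
    stop_cc("presence matrix file must start with a 'taxon' column",
            class = "cladecons_io_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$taxon
  structure(m, class = c("presence_matrix", "matrix"))
}

#' Write a presence matrix as TSV
#' @param pm A `presence_matrix`.
#' @param path Output path.
#' @param comments Extra header comment lines.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path, comments = character()) {
  df <- data.frame(taxon = rownames(pm), unclass(pm), check.names = FALSE)
  write_tsv_commented(df, path, comments)
}

# ---- tree utilities (ape phylo) ---------------------------------------

# Tip indices below each node (including tips themselves), by postorder
# accumulation.
tips_below <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  below <- vector("list", n_all)
  for (i in seq_len(n_tip)) below[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

tree_parent <- function(tree) {
  parent <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

tree_children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[k, 1]]] <- c(ch[[tree$edge[k, 1]]], tree$edge[k, 2])
  }
  ch
}

#' Node display names
#'
#' Tips are named by their labels; internal nodes by their Newick labels
#' where present, otherwise `node<k>` with `k` the ape node number.
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector indexed by ape node number.
#' @export
node_names <- function(tree) {
  n_tip <- ape::Ntip(tree)
  inner <- tree$node.label %||% rep("", tree$Nnode)
  inner[is.na(inner) | inner == ""] <-
    paste0("node", (n_tip + 1):(n_tip + tree$Nnode))[is.na(inner) | inner == ""]
  c(tree$tip.label, inner)
}

#' Resolve a node by name
#' @param tree An `ape::phylo` tree.
#' @param name A tip or internal node name (see [node_names()]).
#' @return The ape node number.
#' @export
node_id <- function(tree, name) {
  idx <- match(name, node_names(tree))
  if (is.na(idx)) {
    stop_cc("no node named '", name, "' in tree",
            class = "cladecons_tree_error")
  }
  idx
}

# ---- Dollo reconstruction ---------------------------------------------

#' Dollo-parsimony reconstruction of clade gains and losses
#'
#' For every clade present somewhere in the matrix, the gain is placed on
#' the branch above the most recent common ancestor of all possessing tips
#' (the branch-circle convention of gene-family complement diagrams), the
#' clade is inferred present at every node from that ancestor down to the
#' possessing tips, and one loss is placed on each maximal subtree
#' containing no possessing tip — the unique minimum-loss solution under the
#' single-gain constraint. A clade present nowhere is skipped with a log
#' message.
#'
#' @param tree A rooted `ape::phylo` tree whose tips cover all taxa in `pm`.
#' @param pm A `presence_matrix` (presence = count > 0). Tips without a row
#'   are treated as reliably lacking every clade.
#' @param unreliable_absence Taxa whose absences reflect sparse sequence
#'   data rather than true loss (e.g. transcriptome-only lineages): they are
#'   excluded from loss inference, so a subtree whose only non-possessing
#'   tips are unreliable incurs no loss and is inferred present
#'   (flagged as inferred-only).
#'
#' @return A list of class `complement_reconstruction`: `tree`,
#'   `node_states` (logical node x clade matrix, rows named by
#'   [node_names()]), `inferred_only` (logical matrix flagging presences
#'   not witnessed by any possessing tip in the node's own subtree), and
#'   `events` (data.frame `clade`, `parent`, `child`, `event`; the gain of a
#'   clade spanning the whole tree is recorded on the root branch with
#'   `parent = "root"`).
#' @export
dollo_reconstruct <- function(tree, pm, unreliable_absence = character()) {
  if (!inherits(tree, "phylo")) {
    stop_cc("tree must be a phylo object", class = "cladecons_tree_error")
  }
  # ape's basal node is taken as the root; a basal polytomy (e.g. a star
  # taxonomy) is acceptable even though ape calls such trees unrooted.
  taxa <- rownames(pm)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0) {
    stop_cc("taxa not on the tree: ", paste(unknown, collapse = ", "),
            class = "cladecons_tree_error")
  }
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  names_all <- node_names(tree)
  below <- tips_below(tree)
  children <- tree_children(tree)
  parent <- tree_parent(tree)

  free_tips <- match(intersect(unreliable_absence, tree$tip.label),
                     tree$tip.label)
  clades <- colnames(pm)
  node_states <- matrix(FALSE, n_all, length(clades),
                        dimnames = list(names_all, clades))
  inferred_only <- node_states
  events <- list()

  for (cl in clades) {
    present_taxa <- taxa[pm[, cl] > 0]
    if (length(present_taxa) == 0) {
      cc_log(sprintf("clade %s present nowhere; skipped", cl), quiet = TRUE)
      next
    }
    pres <- match(present_taxa, tree$tip.label)
    free <- setdiff(free_tips, pres)
    gain_node <- if (length(pres) == 1) pres else ape::getMRCA(tree, pres)

    n_pres <- vapply(below, function(t) sum(t %in% pres), integer(1))
    n_relabs <- vapply(below, function(t) {
      sum(!(t %in% pres) & !(t %in% free))
    }, integer(1))

    gain_parent <- if (gain_node == root) "root" else names_all[parent[gain_node]]
    events[[length(events) + 1]] <- data.frame(
      clade = cl, parent = gain_parent, child = names_all[gain_node],
      event = "gain")

    # Top-down sweep from the gain node.
    state <- rep(NA, n_all)   # NA = untouched, TRUE/FALSE below gain
    state[gain_node] <- TRUE
    wit <- rep(FALSE, n_all)  # presence witnessed by a tip in own subtree
    wit[gain_node] <- TRUE
    queue <- gain_node
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in children[[u]]) {
        if (n_pres[v] > 0) {
          state[v] <- TRUE; wit[v] <- TRUE
          queue <- c(queue, v)
        } else if (n_relabs[v] == 0) {
          # only unreliable absences below: no loss, inferred presence
          state[v] <- TRUE
          queue <- c(queue, v)
        } else {
          state[v] <- FALSE
          events[[length(events) + 1]] <- data.frame(
            clade = cl, parent = names_all[u], child = names_all[v],
            event = "loss")
        }
      }
    }
    node_states[which(state), cl] <- TRUE
    inferred_only[which(state & !wit), cl] <- TRUE
  }
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(clade = character(), parent = character(),
               child = character(), event = character())
  structure(list(tree = tree, node_states = node_states,
                 inferred_only = inferred_only, events = events),
            class = "complement_reconstruction")
}

#' @export
print.complement_reconstruction <- function(x, ...) {
  n_gain <- sum(x$events$event == "gain")
  n_loss <- sum(x$events$event == "loss")
  cat(sprintf("Dollo reconstruction: %d clade gain(s), %d loss(es)\n",
              n_gain, n_loss))
  invisible(x)
}

#' Clade complements at named nodes
#'
#' @param rec A `complement_reconstruction`.
#' @param nodes Character vector of node names (see [node_names()]);
#'   requesting a name not on the tree is an error.
#' @return Named list: per node, the character vector of clades inferred
#'   present there.
#' @export
complement_timeline <- function(rec, nodes) {
  out <- lapply(nodes, function(nm) {
    idx <- node_id(rec$tree, nm)
    colnames(rec$node_states)[rec$node_states[idx, ]]
  })
  stats::setNames(out, nodes)
}

#' Rebuild node states from an event list
#'
#' Replays gains and losses on the tree: a clade is present at every node in
#' the subtree under its gain branch, minus the subtrees under its loss
#' branches. Used as an internal-consistency check on reconstructions.
#'
#' @param tree A rooted `ape::phylo` tree.
#' @param events An events data.frame as produced by [dollo_reconstruct()].
#' @return Logical node x clade matrix, rows named by [node_names()].
#' @export
complement_from_events <- function(tree, events) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  names_all <- node_names(tree)
  below_nodes <- function(node) {
    # all nodes (tips + internals) in the subtree rooted at node
    children <- tree_children(tree)
    acc <- integer(0); stack <- node
    while (length(stack) > 0) {
      u <- stack[1]; stack <- stack[-1]
      acc <- c(acc, u); stack <- c(stack, children[[u]])
    }
    acc
  }
  clades <- unique(events$clade)
  m <- matrix(FALSE, n_all, length(clades),
              dimnames = list(names_all, clades))
  for (cl in clades) {
    ev <- events[events$clade == cl, ]
    gain <- ev$child[ev$event == "gain"]
    if (length(gain) != 1) {
      stop_cc("clade ", cl, " must have exactly one gain",
              class = "cladecons_dollo_error")
    }
    present <- below_nodes(node_id(tree, gain))
    for (lost in ev$child[ev$event == "loss"]) {
      present <- setdiff(present, below_nodes(node_id(tree, lost)))
    }
    m[present, cl] <- TRUE
  }
  m
}

#' Write a reconstruction: events TSV and annotated Newick
#'
#' The Newick copy carries gain/loss annotations appended to node labels as
#' `|+clade` / `|-clade` suffixes on the child node of each event branch.
#'
#' @param rec A `complement_reconstruction`.
#' @param events_path Output TSV path for the event list.
#' @param newick_path Optional output path for the annotated tree.
#' @param comments Extra header comment lines for the TSV.
#' @return `events_path`, invisibly.
#' @export
write_complement <- function(rec, events_path, newick_path = NULL,
                             comments = character()) {
  write_tsv_commented(rec$events, events_path, comments)
  if (!is.null(newick_path)) {
    tree <- rec$tree
    names_all <- node_names(tree)
    lab <- names_all
    for (k in seq_len(nrow(rec$events))) {
      ev <- rec$events[k, ]
      idx <- node_id(tree, ev$child)
      lab[idx] <- paste0(lab[idx], "|",
                         if (ev$event == "gain") "+" else "-", ev$clade)
    }
    n_tip <- ape::Ntip(tree)
    tree$tip.label <- lab[seq_len(n_tip)]
    tree$node.label <- lab[(n_tip + 1):length(lab)]
    ape::write.tree(tree, file = newick_path)
  }
  invisible(events_path)
}
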