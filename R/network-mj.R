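# Median-joining haplotype networks (Bandelt-style) on Hamming distances.
# Sites with gaps or N are excluded before networking; character states are
# restricted to A/C/G/T.

# hamming distance matrix between rows of a character matrix
hamming_rows <- function(M) {
  k <- nrow(M)
  d <- matrix(0L, k, k)
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d[a, b] <- d[b, a] <- sum(M[a, ] != M[b, ])
      }
    }
  }
  d
}

# minimum spanning network edges: all edges that occur in some MST
# (Kruskal over weight classes; within a class, an edge is feasible if its
# endpoints lie in different components formed by strictly smaller weights)
msn_edges <- function(d) {
  n <- nrow(d)
  if (n < 2) return(cbind(from = integer(), to = integer(), w = integer()))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  edges <- NULL
  for (wc in unique(w)) {
    sel <- which(w == wc)
    feas <- logical(length(sel))
    roots <- cbind(vapply(pairs[sel, 1], find, 1L),
                   vapply(pairs[sel, 2], find, 1L))
    feas <- roots[, 1] != roots[, 2]
    if (any(feas)) {
      edges <- rbind(edges, cbind(pairs[sel[feas], , drop = FALSE], wc))
      for (e in sel[feas]) {  # merge after collecting the whole class
        ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
        if (ra != rb) comp[ra] <- rb
      }
    }
  }
  colnames(edges) <- c("from", "to", "w")
  edges
}

#' Build a median-joining haplotype network
#'
#' Iteratively augments the minimum spanning network over the current
#' sequence set with median (consensus) vectors of linked triplets:
#' in each round, every pair of feasible links sharing a node proposes the
#' site-wise majority sequence of the triplet, and the proposals with the
#' minimal connection cost (within tolerance `epsilon`) are added as
#' inferred, unsampled nodes. The loop stops when no proposal is new, and
#' median nodes that end with degree < 2 are pruned. Tie-breaking (the
#' hub's state at sites where all three sequences differ, lexicographic
#' ordering of candidates) is deterministic, so equal inputs give equal
#' networks.
#'
#' @param haps a `haplotype_set` from [em_phase()], or a named character
#'   vector of equal-length sequences.
#' @param epsilon tolerance on the connection cost of retained median
#'   proposals (0 = strict minimum).
#' @param max_rounds safety cap on augmentation rounds.
#' @return object of class `haplotype_network`: `nodes` (data.frame `node,
#'   is_median, count_<group>...`), `edges` (data.frame `from, to, weight`),
#'   `seqs` (named vector, medians included).
#' @export
build_mj_network <- function(haps, epsilon = 0, max_rounds = 50L) {
  group_counts <- NULL
  if (inherits(haps, "haplotype_set")) {
    hs <- haps
    seqs <- hs$haplotypes
    p <- hs$pairs[hs$pairs$phased, , drop = FALSE]
    grp <- hs$meta$host[match(p$sample_id, hs$meta$sample_id)]
    copies <- data.frame(id = c(p$hap1, p$hap2), group = rep(grp, 2))
    group_counts <- table(copies$id, copies$group)
  } else {
    seqs <- haps
  }
  if (length(seqs) < 2) stop("need >= 2 distinct haplotypes")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must be equal length")
  if (anyDuplicated(seqs)) stop("haplotype sequences must be distinct")
  M <- do.call(rbind, strsplit(unname(seqs), ""))
  keep_sites <- apply(M, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  M <- M[, keep_sites, drop = FALSE]
  node_names <- names(seqs) %||% paste0("h", seq_along(seqs))
  is_median <- rep(FALSE, nrow(M))

  seq_key <- function(m) apply(m, 1, paste, collapse = "")
  for (round in seq_len(max_rounds)) {
    d <- hamming_rows(M)
    ed <- msn_edges(d)
    if (nrow(ed) == 0) break
    adj <- lapply(seq_len(nrow(M)), function(i)
      unique(c(ed[ed[, 1] == i, 2], ed[ed[, 2] == i, 1])))
    cand <- list()
    costs <- numeric(0)
    existing <- seq_key(M)
    for (u in seq_len(nrow(M))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) {
        for (b in (a + 1):length(nb)) {
          v <- nb[a]; wn <- nb[b]
          tri <- M[c(u, v, wn), , drop = FALSE]
          med <- apply(tri, 2, function(col) {
            tb <- table(col)
            if (max(tb) >= 2) names(tb)[which.max(tb)] else col[1]
          })
          key <- paste(med, collapse = "")
          if (key %in% existing) next
          cost <- sum(med != tri[1, ]) + sum(med != tri[2, ]) +
                  sum(med != tri[3, ])
          if (cost >= d[u, v] + d[u, wn]) next  # no improvement via hub
          cand[[length(cand) + 1L]] <- med
          costs <- c(costs, cost)
        }
      }
    }
    if (length(cand) == 0) break
    lambda <- min(costs)
    keys <- vapply(cand, paste, "", collapse = "")
    sel <- which(costs <= lambda + epsilon)
    new_keys <- sort(unique(keys[sel]))
    add <- do.call(rbind, lapply(new_keys, function(k)
      cand[[match(k, keys)]]))
    M <- rbind(M, add)
    node_names <- c(node_names,
                    paste0("mv", seq_len(nrow(M) - length(node_names)) +
                             sum(is_median)))
    is_median <- c(is_median, rep(TRUE, length(new_keys)))
  }

  # final network and pruning of dangling medians
  repeat {
    d <- hamming_rows(M)
    ed <- msn_edges(d)
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(M))
    drop <- which(is_median & deg < 2)
    if (length(drop) == 0) break
    M <- M[-drop, , drop = FALSE]
    node_names <- node_names[-drop]
    is_median <- is_median[-drop]
  }

  full <- character(nrow(M))
  for (i in seq_len(nrow(M))) full[i] <- paste(M[i, ], collapse = "")
  names(full) <- node_names
  nodes <- data.frame(node = node_names, is_median = is_median,
                      stringsAsFactors = FALSE)
  if (!is.null(group_counts)) {
    for (g in colnames(group_counts)) {
      cnt <- rep(0L, nrow(nodes))
      obs <- match(rownames(group_counts), nodes$node)
      cnt[obs[!is.na(obs)]] <- group_counts[!is.na(obs), g]
      nodes[[paste0("count_", g)]] <- cnt
    }
  }
  edges <- data.frame(from = node_names[ed[, 1]], to = node_names[ed[, 2]],
                      weight = ed[, 3], stringsAsFactors = FALSE)
  orig_positions <- if (inherits(haps, "haplotype_set")) hs$snp_pos
                    else seq_len(nchar(seqs[[1]]))
  structure(list(nodes = nodes, edges = edges, seqs = full,
                 epsilon = epsilon, kept_sites = which(keep_sites),
                 site_positions = orig_positions[keep_sites]),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes (%d median), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_median), nrow(x$edges)))
  invisible(x)
}

#' Annotate the root-adjacent node(s) of a network
#'
#' Marks the observed haplotype node(s) minimising the total Hamming
#' distance to a set of outgroup sequences (annotation only; no edge is
#' added). Ties are kept, not broken.
#'
#' @param network a [build_mj_network()] result.
#' @param outgroup_seqs named character vector, same alignment length as
#'   the haplotypes the network was built from.
#' @return the network with a logical `root_adjacent` node column and a
#'   `root_distance` attribute column.
#' @export
annotate_root <- function(network, outgroup_seqs) {
  if (length(outgroup_seqs) == 0) stop("empty outgroup set")
  obs <- which(!network$nodes$is_median)
  og <- do.call(rbind, strsplit(unname(outgroup_seqs), ""))
  node_seqs <- do.call(rbind, strsplit(unname(network$seqs[obs]), ""))
  if (ncol(og) == nchar(network$seqs[1])) {
    # outgroups given on the network's (filtered) site set
    ogk <- og
  } else if (ncol(og) >= max(network$site_positions)) {
    # full-length outgroups: restrict to the network's alignment columns
    ogk <- og[, network$site_positions, drop = FALSE]
  } else {
    stop("outgroup sequences must match the haplotype alignment length")
  }
  if (ncol(ogk) != ncol(node_seqs))
    stop("outgroup sequences must match the haplotype alignment length")
  tot <- vapply(seq_along(obs), function(i)
    sum(ogk != matrix(node_seqs[i, ], nrow(ogk), ncol(ogk), byrow = TRUE)),
    0)
  best <- tot == min(tot)
  network$nodes$root_adjacent <- FALSE
  network$nodes$root_adjacent[obs[best]] <- TRUE
  network$nodes$root_distance <- NA_real_
  network$nodes$root_distance[obs] <- tot
  network
}

# igraph view of a network
network_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Export a haplotype network
#'
#' @param network a [build_mj_network()] result.
#' @param path output path (for `tsv`, the prefix of `<path>_nodes.tsv` and
#'   `<path>_edges.tsv`).
#' @param format `"graphml"`, `"dot"` or `"tsv"`.
#' @return written path(s), invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "dot",
                                                     "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    pn <- paste0(path, "_nodes.tsv")
    pe <- paste0(path, "_edges.tsv")
    utils::write.table(network$nodes, pn, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$edges, pe, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(c(pn, pe)))
  }
  if (format == "dot") {
    # the dot writer has no boolean attribute type
    network$nodes$is_median <- as.integer(network$nodes$is_median)
    if (!is.null(network$nodes$root_adjacent))
      network$nodes$root_adjacent <- as.integer(network$nodes$root_adjacent)
  }
  g <- network_igraph(network)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
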