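# Variable-group agglomerative hierarchical clustering.
#
# Unlike pair-group agglomeration, every cluster tied at the minimal
# inter-cluster distance merges in one step, which can create nodes with
# more than two children (a multidendrogram) and makes the result
# independent of input order. Each internal node carries an agglomeration
# band [band_low, band_high]: the minimum and maximum pairwise linkage
# distance among the clusters fused at that node (degenerate when there
# is no tie).

LINKAGE_METHODS <- c("single", "complete", "average_unweighted",
                     "average_weighted", "joint_between_within")

#' Specify a linkage function
#'
#' @param method One of `"single"`, `"complete"`, `"average_unweighted"`
#'   (UPGMA: means weighted by cluster size), `"average_weighted"` (WPGMA:
#'   plain mean over member clusters), `"joint_between_within"` (square
#'   root of the mean squared leaf-to-leaf dissimilarity over all pairs
#'   drawn from the union of the two clusters, between and within alike).
#' @param tie_epsilon Relative tolerance for detecting tied minimal
#'   distances (default `1e-9`); exact ties are always caught.
#' @return An object of class `LinkageSpec`.
#' @export
linkage_spec <- function(method = LINKAGE_METHODS, tie_epsilon = 1e-9) {
  method <- match.arg(method)
  if (tie_epsilon < 0) ct_usage_error("tie_epsilon must be >= 0")
  structure(list(method = method, tie_epsilon = tie_epsilon),
            class = "LinkageSpec")
}

#' Linkage distance from a merged cluster to an outside cluster
#'
#' Combines the distances from the members of a freshly merged cluster to
#' some other cluster K into the distance of the merged cluster to K:
#' minimum (single), maximum (complete), size-weighted mean
#' (average_unweighted / UPGMA) or plain mean (average_weighted / WPGMA).
#' The joint between-within linkage is not expressible from member
#' distances alone; it pools squared leaf-to-leaf dissimilarities and is
#' computed inside [cluster_multidendrogram()].
#'
#' @param method Linkage method name.
#' @param d Numeric vector: distance of each member cluster to K.
#' @param sizes Integer vector of member cluster sizes (leaf counts).
#' @return The merged-to-K linkage distance.
#' @export
linkage_update <- function(method, d, sizes = rep(1L, length(d))) {
  switch(method,
    single = min(d),
    complete = max(d),
    average_unweighted = sum(sizes * d) / sum(sizes),
    average_weighted = mean(d),
    joint_between_within = ct_usage_error(
      "joint_between_within pools leaf-level dissimilarities; see cluster_multidendrogram()"),
    ct_usage_error(paste0("unknown linkage method: ", method)))
}

# distance between two clusters given their leaf index sets, computed from
# the original leaf-level matrix (used for the pooled JBW linkage)
jbw_distance <- function(M, leaves_u, leaves_k) {
  all <- c(leaves_u, leaves_k)
  pairs <- utils::combn(all, 2L)
  sqrt(mean(M[cbind(pairs[1, ], pairs[2, ])]^2))
}

new_leaf_node <- function(name) {
  list(leaf_name = name, leaves = name)
}

is_leaf_node <- function(node) !is.null(node$leaf_name)

#' Cluster a dissimilarity matrix into a multidendrogram
#'
#' Agglomerates iteratively: find the global minimum inter-cluster
#' distance `d*`; connect every cluster pair whose linkage distance lies
#' within the tie tolerance of `d*`; merge each connected component of
#' that graph into one node with `band_low = d*` and `band_high` the
#' maximum pairwise linkage distance inside the component; update
#' distances per the linkage method; repeat until one cluster remains.
#' With no ties this reduces to ordinary pair-group agglomeration; with
#' ties the simultaneous merge is what makes the output invariant to the
#' input order of the leaves.
#'
#' @param M Symmetric dissimilarity matrix with zero diagonal and leaf
#'   names as dimnames (e.g. from [build_matrix()]).
#' @param link A [linkage_spec()], or a method name.
#' @return An object of class `multidendrogram`: a rooted node tree
#'   (internal nodes hold `children`, `band_low`, `band_high`) plus the
#'   leaf name vector and the linkage method.
#' @export
cluster_multidendrogram <- function(M, link = linkage_spec("average_unweighted")) {
  if (is.character(link)) link <- linkage_spec(link)
  M <- unclass(M)
  n <- nrow(M)
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("L", seq_len(n))
  }
  if (n < 2L) ct_usage_error("need >= 2 leaves to cluster")
  if (!isTRUE(all.equal(M, t(M))) || any(diag(M) != 0)) {
    ct_usage_error("matrix must be symmetric with a zero diagonal")
  }
  if (any(M < 0)) ct_usage_error("dissimilarities must be non-negative")

  leaf_names <- rownames(M)
  nodes <- lapply(leaf_names, new_leaf_node)       # active clusters
  leafsets <- lapply(seq_len(n), function(i) i)     # leaf indices per cluster
  D <- M                                            # current cluster distances
  method <- link$method

  while (length(nodes) > 1L) {
    nc <- length(nodes)
    off <- D; diag(off) <- Inf
    dstar <- min(off)
    tol <- link$tie_epsilon * max(abs(dstar), 1)
    tied <- off <= dstar + tol

    # connected components of the tie graph (clusters with no tie edge
    # remain singleton components and survive this round unmerged)
    comp <- seq_len(nc)
    repeat {
      changed <- FALSE
      for (i in seq_len(nc)) {
        nb <- which(tied[i, ])
        if (length(nb) > 0L) {
          target <- min(comp[c(i, nb)])
          if (any(comp[c(i, nb)] != target)) {
            comp[c(i, nb)] <- target
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }

    groups <- split(seq_len(nc), comp)
    new_nodes <- list(); new_leafsets <- list()
    origin <- list()  # member indices in the old cluster list
    for (grp in groups) {
      if (length(grp) == 1L) {
        new_nodes[[length(new_nodes) + 1L]] <- nodes[[grp]]
        new_leafsets[[length(new_leafsets) + 1L]] <- leafsets[[grp]]
        origin[[length(origin) + 1L]] <- grp
      } else {
        inside <- D[grp, grp, drop = FALSE]
        band_high <- max(inside[upper.tri(inside)])
        node <- list(children = nodes[grp],
                     band_low = dstar, band_high = band_high)
        node$leaves <- unlist(lapply(nodes[grp], function(x) x$leaves))
        new_nodes[[length(new_nodes) + 1L]] <- node
        new_leafsets[[length(new_leafsets) + 1L]] <-
          unlist(leafsets[grp], use.names = FALSE)
        origin[[length(origin) + 1L]] <- grp
      }
    }

    nn <- length(new_nodes)
    Dn <- matrix(0, nn, nn)
    sizes_old <- vapply(leafsets, length, integer(1))
    for (i in seq_len(nn - 1L)) {
      for (j in (i + 1L):nn) {
        gi <- origin[[i]]; gj <- origin[[j]]
        if (length(gi) == 1L && length(gj) == 1L) {
          v <- D[gi, gj]
        } else if (method == "joint_between_within") {
          v <- jbw_distance(M, new_leafsets[[i]], new_leafsets[[j]])
        } else {
          # fold member-to-member old distances pairwise: first collapse
          # over gi members for each gj member, then over gj members
          dij <- vapply(gj, function(b) {
            linkage_update(method, D[gi, b], sizes_old[gi])
          }, numeric(1))
          v <- linkage_update(method, dij, vapply(gj, function(b)
            sizes_old[b], integer(1)))
        }
        Dn[i, j] <- v; Dn[j, i] <- v
      }
    }
    nodes <- new_nodes
    leafsets <- new_leafsets
    D <- Dn
  }

  root <- nodes[[1]]
  structure(list(root = root, leaves = leaf_names, method = method,
                 tie_epsilon = link$tie_epsilon),
            class = "multidendrogram")
}

#' @export
print.multidendrogram <- function(x, ...) {
  cat(sprintf("multidendrogram: %d leaves, %s linkage\n",
              length(x$leaves), x$method))
  cat(to_newick(x), "\n")
  invisible(x)
}

node_height <- function(node, mode) {
  if (is_leaf_node(node)) return(0)
  if (mode == "band_mid") (node$band_low + node$band_high) / 2 else node$band_low
}

newick_label <- function(name) {
  name <- gsub("\\s+", "_", name)
  if (grepl("[():,;\\[\\]']", name)) {
    paste0("'", gsub("'", "''", name), "'")
  } else {
    name
  }
}

fmt_bl <- function(x) {
  # fixed formatting keeps output byte-identical across runs
  sub("\\.$", "", sub("0+$", "", sprintf("%.10f", x)))
}

#' Export a multidendrogram as Newick
#'
#' Node heights are the agglomeration-band minima by default (`band_low`,
#' the threshold at which the merge happened) or band midpoints; leaves
#' sit at height 0 and branch lengths are parent minus child height.
#' Multifurcations are preserved; children are ordered by their smallest
#' leaf name so output is reproducible.
#'
#' @param tree A `multidendrogram`.
#' @param height_mode `"band_low"` (default) or `"band_mid"`.
#' @return A single Newick string ending in `";"`.
#' @export
to_newick <- function(tree, height_mode = c("band_low", "band_mid")) {
  height_mode <- match.arg(height_mode)
  rec <- function(node, parent_h) {
    h <- node_height(node, height_mode)
    bl <- parent_h - h
    if (is_leaf_node(node)) {
      return(paste0(newick_label(node$leaf_name), ":", fmt_bl(bl)))
    }
    kids <- node$children
    ord <- order(vapply(kids, function(k) min(k$leaves), character(1)),
                 method = "radix")
    inner <- paste(vapply(kids[ord], rec, character(1), parent_h = h),
                   collapse = ",")
    paste0("(", inner, "):", fmt_bl(bl))
  }
  root_h <- node_height(tree$root, height_mode)
  if (is_leaf_node(tree$root)) {
    return(paste0(newick_label(tree$root$leaf_name), ";"))
  }
  kids <- tree$root$children
  ord <- order(vapply(kids, function(k) min(k$leaves), character(1)),
               method = "radix")
  inner <- paste(vapply(kids[ord], rec, character(1), parent_h = root_h),
                 collapse = ",")
  paste0("(", inner, ");")
}

#' Write a multidendrogram to a Newick file
#'
#' @param tree A `multidendrogram`.
#' @param path Output path.
#' @param height_mode Passed to [to_newick()].
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, height_mode = "band_low") {
  writeLines(to_newick(tree, height_mode), path)
  invisible(path)
}

#' Dump a multidendrogram as JSON
#'
#' Serializes the node structure with `band_low`/`band_high` per internal
#' node, which Newick cannot carry.
#'
#' @param tree A `multidendrogram`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string, or `path` invisibly.
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (is_leaf_node(node)) return(list(leaf = node$leaf_name))
    list(band_low = node$band_low, band_high = node$band_high,
         children = lapply(node$children, strip))
  }
  js <- jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Filter tree leaves by name
#'
#' Case-insensitive substring match on leaf names, the semantics of the
#' viewer's leaf search bar; an empty filter selects every leaf ("select
#' all").
#'
#' @param tree A `multidendrogram`.
#' @param name_filter Substring to match; `""` selects all leaves.
#' @return Character vector of matching leaf names, in leaf order.
#' @export
select_leaves <- function(tree, name_filter = "") {
  if (!nzchar(name_filter)) return(tree$leaves)
  tree$leaves[grepl(tolower(name_filter), tolower(tree$leaves), fixed = TRUE)]
}

# All internal nodes of a tree as a flat list (root first), used by tests
# and by the acceptance checks on tree shape.
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is_leaf_node(node)) return(invisible(NULL))
    out[[length(out) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' Leaf sets of the maximal non-trivial subtrees
#'
#' Returns the leaf set of each child of the root that is itself an
#' internal node (a "major out-branch" of the context tree).
#'
#' @param tree A `multidendrogram`.
#' @return List of character vectors of leaf names.
#' @export
major_branches <- function(tree) {
  if (is_leaf_node(tree$root)) return(list())
  kids <- Filter(Negate(is_leaf_node), tree$root$children)
  lapply(kids, function(k) sort(k$leaves))
}
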