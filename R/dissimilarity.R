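# Context-to-context dissimilarity metrics and the pairwise matrix.
#
# Two metric families: set-based gene-content measures (Dice, Jaccard)
# over the identity keys of a grouping's genes, and coordinate-based
# measures (moving distances over intergenic spacing, total span length).

#' Identity keys of a grouping's genes
#'
#' Reduces a grouping to the set of identity keys used by the set-based
#' metrics: homology-cluster IDs, or annotation strings normalized by
#' lowercasing and whitespace collapsing. Duplicate keys within one
#' grouping count once (set semantics). Genes without a homology cluster
#' carry no key under the `homology_cluster` key.
#'
#' @param grouping A [ContextGrouping].
#' @param key `"homology_cluster"` or `"annotation"`.
#' @param reduce Reduce the multiset to a set (default, the behaviour the
#'   set metrics assume).
#' @return Character vector of keys.
#' @export
identity_keys <- function(grouping, key = c("homology_cluster", "annotation"),
                          reduce = TRUE) {
  key <- match.arg(key)
  v <- if (key == "homology_cluster") {
    cl <- grouping$genes$cluster
    as.character(cl[!is.na(cl)])
  } else {
    normalize_annotation(grouping$genes$annotation)
  }
  if (reduce) unique(v) else v
}

normalize_annotation <- function(x) {
  trimws(gsub("\\s+", " ", tolower(x)))
}

#' Dice dissimilarity between two gene-identity sets
#'
#' `1 - 2|a n b| / (|a| + |b|)`; two empty sets are identical (0).
#'
#' @param a,b Vectors of identity keys (duplicates are ignored).
#' @return Dissimilarity in `[0, 1]`.
#' @export
dice_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(0)
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Jaccard dissimilarity between two gene-identity sets
#'
#' `1 - |a n b| / |a u b|`; two empty sets are identical (0).
#'
#' @inheritParams dice_dissimilarity
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(0)
  1 - length(intersect(a, b)) / length(union(a, b))
}

# Gene order of a grouping for spacing comparison. With mirror = TRUE the
# grouping is reversed when a strict majority of its genes lie on the
# minus strand, paralleling the viewer's strand normalization; ties keep
# the reported orientation. Mirroring a context reverses gene order but
# preserves every pairwise intergenic gap, so only the order needs
# flipping here.
oriented_genes <- function(grouping, mirror = TRUE) {
  g <- grouping$genes
  if (mirror && sum(g$strand == "-") * 2L > nrow(g)) {
    g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  }
  g
}

# Positional multiset matching of shared keys: for each key keep the first
# min(count_a, count_b) occurrences in each grouping, in gene order.
shared_subsequence <- function(keys_a, keys_b) {
  u <- union(keys_a, keys_b)
  counts <- stats::setNames(
    pmin(vapply(u, function(k) sum(keys_a == k), integer(1)),
         vapply(u, function(k) sum(keys_b == k), integer(1))),
    u)
  pick <- function(keys) {
    seen <- stats::setNames(rep(0L, length(counts)), names(counts))
    idx <- integer(0)
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (seen[k] < counts[k]) {
        seen[k] <- seen[k] + 1L
        idx <- c(idx, i)
      }
    }
    idx
  }
  list(a = pick(keys_a), b = pick(keys_b))
}

#' Moving-distances dissimilarity
#'
#' Compares two groupings by gene order and intergenic spacing: the
#' groupings are restricted to the identity keys they share (repeated keys
#' matched in positional order), the intergenic gap between consecutive
#' shared genes (nucleotides strictly between their facing boundaries) is
#' computed within each grouping, and the dissimilarity is the mean
#' absolute difference of these gaps, plus `penalty` nucleotides per
#' unshared gene. Groupings sharing fewer than two genes are maximally
#' different: the sentinel `cap` is returned. Identical groupings score 0.
#'
#' @param a,b [ContextGrouping] objects.
#' @param key Comparison key, as in [identity_keys()].
#' @param penalty Nucleotide penalty per unshared gene (default 0).
#' @param cap Sentinel returned when fewer than 2 genes are shared
#'   (default 10000 nt).
#' @param mirror Reverse a grouping whose genes are predominantly on the
#'   minus strand before comparing (default `TRUE`).
#' @return Dissimilarity `>= 0`, in nucleotides.
#' @export
moving_distances <- function(a, b, key = "homology_cluster",
                             penalty = 0, cap = 10000, mirror = TRUE) {
  ga <- oriented_genes(a, mirror)
  gb <- oriented_genes(b, mirror)
  keyize <- function(g) {
    if (key == "homology_cluster") {
      ifelse(is.na(g$cluster), paste0("\r", seq_len(nrow(g))),
             as.character(g$cluster))
    } else {
      normalize_annotation(g$annotation)
    }
  }
  ka <- keyize(ga); kb <- keyize(gb)
  sub <- shared_subsequence(ka, kb)
  m <- length(sub$a)
  unshared <- (nrow(ga) - m) + (nrow(gb) - m)
  if (m < 2L) return(cap)
  gaps <- function(g, idx) {
    # facing boundaries: later start minus earlier end minus 1, for each
    # consecutive pair of the shared subsequence in listed orientation
    first <- idx[-length(idx)]; second <- idx[-1]
    e1 <- ifelse(g$start[first] <= g$start[second], g$end[first], g$end[second])
    s2 <- pmax(g$start[first], g$start[second])
    s2 - e1 - 1
  }
  d <- mean(abs(gaps(ga, sub$a) - gaps(gb, sub$b)))
  d + penalty * unshared
}

#' Total-length dissimilarity
#'
#' Absolute difference of the groupings' sizes: by default the span
#' (envelope) length `span_end - span_start + 1`; `mode = "gene_sum"`
#' uses the summed gene lengths instead. Useful for contexts that differ
#' mainly in the size of one or a few genes.
#'
#' @param a,b [ContextGrouping] objects.
#' @param mode `"span"` (default) or `"gene_sum"`.
#' @return Dissimilarity `>= 0`, in nucleotides.
#' @export
total_length <- function(a, b, mode = c("span", "gene_sum")) {
  mode <- match.arg(mode)
  len <- function(g) {
    if (mode == "span") g$span_end - g$span_start + 1
    else sum(g$genes$end - g$genes$start + 1)
  }
  abs(len(a) - len(b))
}

#' Build the pairwise dissimilarity matrix over context leaves
#'
#' @param leaves List of `>= 2` named [ContextGrouping] leaves.
#' @param metric One of `"dice"`, `"jaccard"`, `"moving_distances"`,
#'   `"total_length"`.
#' @param key Comparison key for the content-based metrics.
#' @param ... Extra metric parameters (`penalty`, `cap`, `mirror`, `mode`).
#' @return A symmetric numeric matrix with zero diagonal, leaf names as
#'   dimnames, and attributes `metric` and `comparison_key`; class
#'   `DissimilarityMatrix`.
#' @export
build_matrix <- function(leaves,
                         metric = c("dice", "jaccard", "moving_distances",
                                    "total_length"),
                         key = c("homology_cluster", "annotation"), ...) {
  metric <- match.arg(metric)
  key <- match.arg(key)
  n <- length(leaves)
  if (n < 2L) ct_usage_error("need >= 2 leaves to build a matrix")
  nms <- vapply(leaves, function(l) l$leaf_name, character(1))
  if (anyDuplicated(nms)) ct_usage_error("leaf names must be unique")
  pairfun <- switch(metric,
    dice = function(a, b, ...) {
      dice_dissimilarity(identity_keys(a, key), identity_keys(b, key))
    },
    jaccard = function(a, b, ...) {
      jaccard_dissimilarity(identity_keys(a, key), identity_keys(b, key))
    },
    moving_distances = function(a, b, ...) {
      moving_distances(a, b, key = key, ...)
    },
    total_length = function(a, b, ...) total_length(a, b, ...))
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- pairfun(leaves[[i]], leaves[[j]], ...)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, metric = metric, comparison_key = key,
            class = c("DissimilarityMatrix", class(m)))
}

#' Write a dissimilarity matrix as PHYLIP or TSV
#'
#' PHYLIP square format: a line with the leaf count, then one row per
#' leaf (name, then the distances). TSV: header row of leaf names, then
#' name-prefixed rows.
#'
#' @param m A matrix from [build_matrix()].
#' @param path Output path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  nms <- rownames(m)
  fmt_row <- function(i) paste(format(m[i, ], trim = TRUE, digits = 10),
                               collapse = "\t")
  lines <- if (format == "phylip") {
    c(as.character(nrow(m)),
      vapply(seq_len(nrow(m)),
             function(i) paste(nms[i], fmt_row(i), sep = "\t"), character(1)))
  } else {
    c(paste(c("", nms), collapse = "\t"),
      vapply(seq_len(nrow(m)),
             function(i) paste(nms[i], fmt_row(i), sep = "\t"), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
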