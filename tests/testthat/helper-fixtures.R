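# Shared test helpers: compact genome builders, random fixtures, and the
# independent oracles the clustering and metric tests compare against.

# Build a Genome from parallel vectors; defaults keep call sites short.
mk_genome <- function(start, end, strand = rep("+", length(start)),
                      contig = rep("c1", length(start)),
                      cluster = rep(NA_integer_, length(start)),
                      annotation = sprintf("protein %d", seq_along(start)),
                      gene_id = sprintf("g%d", seq_along(start)),
                      species = "spA") {
  Genome(species, data.frame(gene_id = gene_id, contig = contig,
                             start = as.integer(start), end = as.integer(end),
                             strand = strand, annotation = annotation,
                             cluster = cluster, stringsAsFactors = FALSE))
}

# A ContextGrouping straight from coordinate vectors.
mk_grouping <- function(start, end, strand = rep("+", length(start)),
                        cluster = seq_along(start),
                        annotation = sprintf("protein %d", seq_along(start)),
                        species = "spA", leaf = "spA-1") {
  g <- mk_genome(start, end, strand, cluster = cluster,
                 annotation = annotation, species = species)
  ContextGrouping(species, g$features, leaf_name = leaf)
}

# Random genome on 1-2 contigs: positive lengths, sorted, random strands.
random_genome <- function(n = 20, species = "spR") {
  contigs <- sample(c("c1", "c2"), n, replace = TRUE)
  feats <- do.call(rbind, lapply(unique(contigs), function(ct) {
    m <- sum(contigs == ct)
    lens <- sample(200:1200, m, replace = TRUE)
    gaps <- sample(0:150, m, replace = TRUE)
    starts <- cumsum(c(1L, (lens + gaps)[-m]))
    data.frame(contig = ct, start = starts, end = starts + lens - 1L,
               strand = sample(c("+", "-"), m, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  mk_genome(feats$start, feats$end, feats$strand, contig = feats$contig,
            cluster = sample(1:8, n, replace = TRUE), species = species)
}

# Random symmetric dissimilarity matrix; values drawn so that with high
# probability all pairwise linkage minima are distinct (tie-free).
random_dissimilarity <- function(n) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0.05, 1)
  v <- v + t(v)
  rownames(v) <- colnames(v) <- sprintf("L%02d", seq_len(n))
  v
}

# Signature of a tree: one "leafset@height" string per internal node,
# sorted. Two trees with equal signatures have identical topology and
# merge heights (up to the rounding in the signature).
tree_signature <- function(tree) {
  nodes <- contexttrees:::tree_nodes(tree)
  sort(vapply(nodes, function(nd) {
    paste0(paste(sort(nd$leaves), collapse = ","), "@",
           sprintf("%.9f", nd$band_low))
  }, character(1)))
}

# Same signature extracted from an hclust object (the independent
# pair-group oracle for tie-free matrices).
hclust_signature <- function(h, labels) {
  n <- length(labels)
  members <- vector("list", nrow(h$merge))
  sig <- character(nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    get <- function(j) if (j < 0) labels[-j] else members[[j]]
    members[[i]] <- c(get(h$merge[i, 1]), get(h$merge[i, 2]))
    sig[i] <- paste0(paste(sort(members[[i]]), collapse = ","), "@",
                     sprintf("%.9f", h$height[i]))
  }
  sort(sig)
}

# Brute-force moving-distances oracle for groupings with identical gene
# content and order: mean absolute difference of consecutive intergenic
# gaps, computed naively.
bf_moving <- function(a, b) {
  gaps <- function(g) {
    f <- g$genes
    f$start[-1] - f$end[-nrow(f)] - 1
  }
  mean(abs(gaps(a) - gaps(b)))
}

# Flatten a partition (list of ContextGrouping) to a sorted gene_id table.
partition_gene_ids <- function(groupings) {
  sort(unlist(lapply(groupings, function(g) g$genes$gene_id),
              use.names = FALSE))
}
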