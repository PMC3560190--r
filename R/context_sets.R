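# Context sets: schemes that turn a genome's gene list into genomic
# groupings (the future leaves of a context tree), plus query matching.

#' Construct a ContextGrouping
#'
#' An ordered run of genes from one contig of one genome: one genomic
#' context, i.e. one leaf of a context tree. The span is the 1-based
#' inclusive envelope of its genes.
#'
#' @param species_name Species the genes come from.
#' @param genes Data frame of features (same columns as `Genome$features`),
#'   all on one contig.
#' @param leaf_name Optional display name (assigned by [build_context_leaves()]).
#' @return An object of class `ContextGrouping`.
#' @export
ContextGrouping <- function(species_name, genes, leaf_name = NA_character_) {
  if (nrow(genes) == 0L) ct_usage_error("a ContextGrouping needs >= 1 gene")
  if (length(unique(genes$contig)) != 1L) {
    ct_usage_error("all genes of a ContextGrouping must share one contig")
  }
  genes <- genes[order(genes$start, genes$end, method = "radix"), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(species_name = species_name,
                 contig = genes$contig[1],
                 genes = genes,
                 leaf_name = leaf_name,
                 span_start = min(genes$start),
                 span_end = max(genes$end)),
            class = "ContextGrouping")
}

#' @export
print.ContextGrouping <- function(x, ...) {
  cat(sprintf("ContextGrouping '%s' (%s %s:%d-%d, %d gene(s))\n",
              x$leaf_name, x$species_name, x$contig,
              x$span_start, x$span_end, nrow(x$genes)))
  invisible(x)
}

#' Define a context set
#'
#' A named grouping scheme with its parameters. Schemes:
#' \describe{
#'   \item{`single_gene`}{each query match is its own context.}
#'   \item{`operon`}{same-strand runs with intergenic gap `<= threshold`
#'     nucleotides (default 20, the operon-prediction threshold).}
#'   \item{`strand_distance`}{same rule with threshold `distance`; the
#'     "D75" set is this scheme with `distance = 75`.}
#'   \item{`gene_window`}{match plus `k` genes each side on its contig.}
#'   \item{`nt_window`}{all genes overlapping the match extended by
#'     `window` nucleotides each side.}
#'   \item{`custom`}{groupings supplied via `groupings` (see
#'     [parse_custom_groupings()]).}
#' }
#'
#' @param name Display name of the set (e.g. `"D75"`).
#' @param scheme One of the schemes above.
#' @param threshold,distance,k,window Scheme parameters (non-negative
#'   integers).
#' @param groupings For `scheme = "custom"`, a list of [ContextGrouping].
#' @return An object of class `ContextSet`.
#' @export
context_set <- function(name,
                        scheme = c("single_gene", "operon", "gene_window",
                                   "nt_window", "strand_distance", "custom"),
                        threshold = 20L, distance = 75L, k = 1L, window = 0L,
                        groupings = NULL) {
  scheme <- match.arg(scheme)
  chk <- function(v, nm) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != as.integer(v)) {
      ct_usage_error(paste0(nm, " must be a single non-negative integer"))
    }
    as.integer(v)
  }
  params <- switch(scheme,
    single_gene = list(),
    operon = list(threshold = chk(threshold, "threshold")),
    strand_distance = list(distance = chk(distance, "distance")),
    gene_window = list(k = chk(k, "k")),
    nt_window = list(window = chk(window, "window")),
    custom = {
      if (is.null(groupings)) ct_usage_error("custom scheme needs 'groupings'")
      list(groupings = groupings)
    })
  structure(list(name = name, scheme = scheme, params = params),
            class = "ContextSet")
}

#' Define a search query
#'
#' @param mode `"annotation_text"` (substring match against annotation) or
#'   `"homology_cluster_id"` (exact cluster equality).
#' @param value Query string or cluster ID.
#' @param case_sensitive Only used for annotation queries; default off.
#' @return An object of class `ContextQuery`.
#' @export
context_query <- function(mode = c("annotation_text", "homology_cluster_id"),
                          value, case_sensitive = FALSE) {
  mode <- match.arg(mode)
  if (mode == "homology_cluster_id") {
    value <- suppressWarnings(as.integer(value))
    if (is.na(value)) ct_usage_error("cluster query value must be an integer")
  } else {
    value <- as.character(value)
  }
  structure(list(mode = mode, value = value,
                 case_sensitive = isTRUE(case_sensitive)),
            class = "ContextQuery")
}

# Shared grouping kernel: cut the sorted feature list wherever the contig
# changes, the strand flips, or the intergenic gap exceeds the threshold.
# The intergenic gap between consecutive genes is start[i+1] - end[i] - 1
# (nucleotides strictly between them); overlapping genes have negative gap
# and always chain. Returns an integer grouping index per feature row.
strand_run_ids <- function(features, threshold) {
  n <- nrow(features)
  if (n == 0L) return(integer(0))
  gap <- c(Inf, features$start[-1] - features$end[-n] - 1L)
  new_run <- c(TRUE,
               features$contig[-1] != features$contig[-n] |
               features$strand[-1] != features$strand[-n] |
               gap[-1] > threshold)
  cumsum(new_run)
}

group_by_runs <- function(genome, threshold) {
  ids <- strand_run_ids(genome$features, threshold)
  unname(lapply(split(seq_along(ids), ids), function(rows) {
    ContextGrouping(genome$species_name,
                    genome$features[rows, , drop = FALSE])
  }))
}

#' Predict operons by intergenic distance
#'
#' Partitions a genome's genes into putative operons: maximal runs of
#' consecutive same-strand, same-contig genes whose intergenic gaps are all
#' `<= threshold` nucleotides. Every gene lands in exactly one grouping.
#'
#' @param genome A [Genome].
#' @param threshold Intergenic distance threshold in nucleotides
#'   (default 20).
#' @return List of [ContextGrouping] covering all genes.
#' @export
group_operons <- function(genome, threshold = 20L) {
  if (threshold < 0L) ct_usage_error("threshold must be >= 0")
  group_by_runs(genome, threshold)
}

#' Group same-strand genes within a distance
#'
#' The strand-distance scheme: genes on the same strand within `distance`
#' nucleotides of each other chain transitively into one grouping. This is
#' the same kernel as [group_operons()]; the "D75" context set is this
#' scheme with `distance = 75`.
#'
#' @param genome A [Genome].
#' @param distance Maximum intergenic gap in nucleotides.
#' @return List of [ContextGrouping] covering all genes.
#' @export
group_strand_distance <- function(genome, distance = 75L) {
  if (distance < 0L) ct_usage_error("distance must be >= 0")
  group_by_runs(genome, distance)
}

#' Find genes matching a query across genomes
#'
#' Annotation queries use substring matching (case-insensitive unless the
#' query says otherwise); homology queries use exact cluster-ID equality.
#' Matches come back ordered by species input order, then contig, then
#' start.
#'
#' @param genomes List of [Genome] objects (input order is significant).
#' @param hmap A [HomologyMap], or `NULL`. Required for cluster queries
#'   unless clusters were already attached with [assign_homology()].
#' @param query A [ContextQuery].
#' @return Data frame with columns `species_name`, `species_index`,
#'   `row` (feature row within the genome), `gene_id`, `contig`, `start`.
#' @export
match_query <- function(genomes, hmap, query) {
  out <- list()
  for (si in seq_along(genomes)) {
    g <- genomes[[si]]
    f <- g$features
    if (query$mode == "annotation_text") {
      hay <- f$annotation
      needle <- query$value
      if (!query$case_sensitive) {
        hay <- tolower(hay); needle <- tolower(needle)
      }
      hit <- grepl(needle, hay, fixed = TRUE)
    } else {
      cl <- f$cluster
      if (all(is.na(cl))) {
        if (is.null(hmap)) {
          ct_usage_error("homology cluster query requires a homology map")
        }
        cl <- homology_lookup(hmap, g$species_name, f$gene_id)
      }
      hit <- !is.na(cl) & cl == query$value
    }
    rows <- which(hit)
    if (length(rows) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        species_name = g$species_name, species_index = si, row = rows,
        gene_id = f$gene_id[rows], contig = f$contig[rows],
        start = f$start[rows], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(species_name = character(), species_index = integer(),
                      row = integer(), gene_id = character(),
                      contig = character(), start = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$species_index, res$contig, res$start, method = "radix"), ]
  rownames(res) <- NULL
  res
}

#' Name a context-tree leaf
#'
#' Leaves are named by joining the organism name to the serial number of
#' the query match within that organism (counted in genomic order,
#' starting at 1). Whitespace in species names becomes `_` so names stay
#' Newick-safe.
#'
#' @param species_name Organism name.
#' @param serial Match serial within the species (`>= 1`).
#' @return Leaf name, e.g. `"Klebsiella_oxytoca-1"`.
#' @export
name_leaf <- function(species_name, serial) {
  paste0(gsub("\\s+", "_", species_name), "-", as.integer(serial))
}

#' Build the leaves of a context tree
#'
#' Runs the query over all genomes, expands each match into a genomic
#' grouping under the context set's scheme, deduplicates groupings hit by
#' several matches (one context is one leaf no matter how many hits it
#' contains), and assigns leaf names via [name_leaf()]. Serial numbers
#' restart at 1 for every species and every call.
#'
#' @param genomes List of [Genome] objects.
#' @param hmap A [HomologyMap] or `NULL`.
#' @param query A [ContextQuery].
#' @param cs A [ContextSet].
#' @return List of named [ContextGrouping] leaves; empty list when the
#'   query matches nothing.
#' @export
build_context_leaves <- function(genomes, hmap, query, cs) {
  if (!is.null(hmap)) genomes <- lapply(genomes, assign_homology, hmap = hmap)
  matches <- match_query(genomes, hmap, query)
  if (nrow(matches) == 0L) return(list())

  # per-species serials in genomic order (match_query already sorted)
  matches$serial <- stats::ave(seq_len(nrow(matches)), matches$species_index,
                               FUN = seq_along)

  precomp <- NULL
  if (cs$scheme %in% c("operon", "strand_distance")) {
    thr <- if (cs$scheme == "operon") cs$params$threshold else cs$params$distance
    precomp <- lapply(genomes, function(g) {
      list(ids = strand_run_ids(g$features, thr), genome = g)
    })
  }

  leaves <- list()
  seen <- character(0)  # dedup keys: species index + grouping identity
  for (mi in seq_len(nrow(matches))) {
    m <- matches[mi, ]
    g <- genomes[[m$species_index]]
    f <- g$features
    grp_rows <- switch(cs$scheme,
      single_gene = m$row,
      operon = ,
      strand_distance = {
        ids <- precomp[[m$species_index]]$ids
        which(ids == ids[m$row])
      },
      gene_window = {
        on_contig <- which(f$contig == m$contig)
        pos <- match(m$row, on_contig)
        on_contig[max(1L, pos - cs$params$k):min(length(on_contig),
                                                 pos + cs$params$k)]
      },
      nt_window = {
        w <- cs$params$window
        lo <- f$start[m$row] - w
        hi <- f$end[m$row] + w
        which(f$contig == m$contig & f$start <= hi & f$end >= lo)
      },
      custom = NULL)
    if (cs$scheme == "custom") {
      hit <- Filter(function(cg) {
        cg$species_name == m$species_name && m$gene_id %in% cg$genes$gene_id
      }, cs$params$groupings)
      if (length(hit) == 0L) next
      cg <- hit[[1]]
      key <- paste(m$species_index, cg$leaf_name, sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      cg$leaf_name <- name_leaf(m$species_name, m$serial)
      leaves[[length(leaves) + 1L]] <- cg
      next
    }
    key <- paste(m$species_index, paste(grp_rows, collapse = ","), sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    leaves[[length(leaves) + 1L]] <- ContextGrouping(
      m$species_name, f[grp_rows, , drop = FALSE],
      leaf_name = name_leaf(m$species_name, m$serial))
  }
  leaves
}
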