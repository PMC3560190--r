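# Readers and writers for the annotation formats the pipeline consumes:
# per-species GFF files, species mapping files, cross-species homology
# cluster tables, and custom context-grouping tables.

#' Construct a Genome object
#'
#' A `Genome` bundles a species name with its annotated gene features.
#' Features are stored as a data frame with columns `gene_id`, `contig`,
#' `start`, `end`, `strand`, `annotation`, `cluster` (1-based inclusive
#' coordinates as in GFF), sorted by `(contig, start, end)`.
#'
#' @param species_name Character scalar naming the organism.
#' @param features Data frame of gene features (see Details).
#' @param contig_lengths Optional named integer vector of contig lengths.
#' @return An object of class `Genome`.
#' @export
Genome <- function(species_name, features, contig_lengths = NULL) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  needed <- c("gene_id", "contig", "start", "end", "strand", "annotation")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0L) {
    ct_usage_error(paste0("features lacks columns: ",
                          paste(missing_cols, collapse = ", ")))
  }
  if (!"cluster" %in% names(features)) features$cluster <- NA_integer_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$cluster <- as.integer(features$cluster)
  if (any(features$start < 1L)) ct_input_error("start coordinates must be >= 1")
  if (any(features$end < features$start)) {
    ct_input_error("end < start in feature table")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    ct_input_error("strand must be '+' or '-' for every feature")
  }
  if (anyDuplicated(features$gene_id)) {
    dup <- unique(features$gene_id[duplicated(features$gene_id)])
    ct_input_error(paste0("duplicate gene_id: ", paste(dup, collapse = ", ")))
  }
  ord <- order(features$contig, features$start, features$end,
               features$gene_id, method = "radix")
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  structure(list(species_name = species_name,
                 features = features,
                 contig_lengths = contig_lengths),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d features on %d contig(s)\n",
              x$species_name, nrow(x$features),
              length(unique(x$features$contig))))
  invisible(x)
}

# Pull one attribute value out of a GFF attribute column, trying GFF3
# "key=value" first, then GFF2 "key value" / 'key "value"'. Dialects are
# detected per token so files mixing conventions still parse.
gff_attr <- function(tokens, keys) {
  for (key in keys) {
    for (tok in tokens) {
      m <- regmatches(tok, regexec(paste0("^\\s*", key, "\\s*=\\s*(.*)$"), tok))[[1]]
      if (length(m) == 2L) return(gff_unquote(m[2]))
      m <- regmatches(tok, regexec(paste0("^\\s*", key, "\\s+(.*)$"), tok))[[1]]
      if (length(m) == 2L) return(gff_unquote(m[2]))
    }
  }
  NA_character_
}

gff_unquote <- function(x) {
  x <- trimws(x)
  x <- sub('^"(.*)"$', "\\1", x)
  # percent-decoding of the characters GFF3 requires to be escaped
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  x <- gsub("%25", "%", x, fixed = TRUE)
  x
}

#' Parse a GFF annotation file into a Genome
#'
#' Accepts 9-column tab-delimited GFF, versions 2 and 3; the attribute
#' dialect (`key=value;` vs `key value;`) is auto-detected per record, so
#' mixed-dialect files parse. Only records whose feature type is in
#' `retain_types` are kept; when a `gene` and a `CDS` record share an ID
#' the `gene` record wins. The gene identifier is taken from the first of
#' `locus_tag`, `ID`, `gene_id`, `gene` present, the annotation text from
#' the first of `product`, `Note`, `annotation`, `description`.
#'
#' @param path Path to the GFF file.
#' @param species_name Species name stored on the returned `Genome`.
#' @param retain_types Feature types (column 3) to keep.
#' @return A [Genome].
#' @export
parse_gff <- function(path, species_name,
                      retain_types = c("gene", "CDS")) {
  if (!file.exists(path)) {
    ct_input_error(paste0("GFF file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) {
      ct_parse_error(sprintf("line %d: expected 9 tab-delimited columns, got %d",
                             i, length(fields)), line = i)
    }
    type <- fields[3]
    if (!type %in% retain_types) next
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end)) {
      ct_parse_error(sprintf("line %d: non-integer coordinates '%s'..'%s'",
                             i, fields[4], fields[5]), line = i)
    }
    if (end < start) {
      ct_parse_error(sprintf("line %d: end (%d) < start (%d)", i, end, start),
                     line = i)
    }
    strand <- fields[7]
    if (!strand %in% c("+", "-")) {
      ct_parse_error(sprintf(
        "line %d: strand '%s' not allowed (contexts require '+' or '-')",
        i, strand), line = i)
    }
    tokens <- strsplit(fields[9], ";", fixed = TRUE)[[1]]
    gene_id <- gff_attr(tokens, c("locus_tag", "ID", "gene_id", "gene"))
    if (is.na(gene_id)) {
      ct_parse_error(sprintf("line %d: no gene identifier attribute found", i),
                     line = i)
    }
    annot <- gff_attr(tokens, c("product", "Note", "annotation", "description"))
    if (is.na(annot)) annot <- ""
    recs[[k]] <- data.frame(gene_id = gene_id, contig = fields[1],
                            start = start, end = end, strand = strand,
                            annotation = annot, type = type,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    feats <- data.frame(gene_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), annotation = character(),
                        stringsAsFactors = FALSE)
    return(Genome(species_name, feats))
  }
  feats <- do.call(rbind, recs)
  # gene record wins over CDS sharing its ID; otherwise first occurrence wins
  feats <- feats[order(match(feats$type, c("gene", setdiff(retain_types, "gene")))), ]
  feats <- feats[!duplicated(feats$gene_id), ]
  feats$type <- NULL
  Genome(species_name, feats)
}

#' Write a Genome back to GFF3
#'
#' Emits one 9-column `gene` record per feature; `parse_gff()` on the
#' output reconstructs the Genome field-by-field (cluster assignments are
#' not part of GFF and are dropped).
#'
#' @param genome A [Genome].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genome, path) {
  f <- genome$features
  esc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x
  }
  attrs <- paste0("ID=", esc(f$gene_id),
                  ifelse(nchar(f$annotation) > 0L,
                         paste0(";product=", esc(f$annotation)), ""))
  lines <- c("##gff-version 3",
             paste(f$contig, "contexttrees", "gene", f$start, f$end, ".",
                   f$strand, ".", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a species mapping file
#'
#' Two-column tab-delimited file: species name, path of that species' GFF
#' file. Row order is preserved; it fixes the species order used for leaf
#' naming downstream.
#'
#' @param path Path to the mapping file.
#' @return Data frame with columns `species_name`, `gff_path`.
#' @export
parse_species_mapping <- function(path) {
  if (!file.exists(path)) {
    ct_input_error(paste0("mapping file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  out <- data.frame(species_name = character(), gff_path = character(),
                    stringsAsFactors = FALSE)
  for (i in idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      ct_parse_error(sprintf("line %d: expected 2 tab-delimited columns, got %d",
                             i, length(fields)), line = i)
    }
    out <- rbind(out, data.frame(species_name = fields[1], gff_path = fields[2],
                                 stringsAsFactors = FALSE))
  }
  if (anyDuplicated(out$species_name)) {
    dup <- unique(out$species_name[duplicated(out$species_name)])
    ct_input_error(paste0("duplicate species name(s) in mapping file: ",
                          paste(dup, collapse = ", ")))
  }
  rownames(out) <- NULL
  out
}

hmap_key <- function(species, gene_id) paste(species, gene_id, sep = "\t")

#' Construct a HomologyMap
#'
#' Maps `(species, gene_id)` pairs to integer homology-cluster IDs, as
#' produced by an upstream sequence-clustering pipeline (e.g. BLAST + MCL).
#'
#' @param species Character vector of species names.
#' @param gene_id Character vector of gene identifiers.
#' @param cluster Integer vector of cluster IDs.
#' @return An object of class `HomologyMap` (named integer vector keyed by
#'   species and gene).
#' @export
HomologyMap <- function(species, gene_id, cluster) {
  stopifnot(length(species) == length(gene_id),
            length(gene_id) == length(cluster))
  key <- hmap_key(species, gene_id)
  cluster <- as.integer(cluster)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(cluster[key == k])) > 1L
    }, logical(1))
    if (any(conflict)) {
      genes <- sub("\t", ":", names(conflict)[conflict], fixed = TRUE)
      ct_input_error(paste0("gene(s) assigned to more than one cluster: ",
                            paste(genes, collapse = ", ")))
    }
    keep <- !duplicated(key)
    key <- key[keep]
    cluster <- cluster[keep]
  }
  structure(stats::setNames(cluster, key), class = "HomologyMap")
}

#' Look up homology clusters for genes of one species
#'
#' @param hmap A [HomologyMap].
#' @param species Species name.
#' @param gene_id Character vector of gene IDs.
#' @return Integer vector of cluster IDs (`NA` where unassigned).
#' @export
homology_lookup <- function(hmap, species, gene_id) {
  unname(unclass(hmap)[hmap_key(species, gene_id)])
}

#' Parse a homology-cluster table
#'
#' Two tab-delimited layouts are supported:
#' \describe{
#'   \item{`"long"`}{one row per gene: `species<TAB>gene_id<TAB>cluster`.}
#'   \item{`"cluster_per_line"`}{one row per cluster:
#'     `cluster<TAB>species|gene<TAB>species|gene...`.}
#' }
#' Both layouts encoding the same clustering yield the same map. A gene
#' assigned to two different clusters is rejected. Further layouts can be
#' added by extending the `format_id` dispatch here.
#'
#' @param path Path to the table.
#' @param format_id One of `"long"`, `"cluster_per_line"`.
#' @return A [HomologyMap].
#' @export
parse_homology_table <- function(path, format_id = c("long", "cluster_per_line")) {
  format_id <- match.arg(format_id)
  if (!file.exists(path)) {
    ct_input_error(paste0("homology table not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  species <- character(0); gene <- character(0); clus <- integer(0)
  for (i in idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (format_id == "long") {
      if (length(fields) != 3L) {
        ct_parse_error(sprintf("line %d: expected 3 columns (species, gene, cluster)", i),
                       line = i)
      }
      cl <- suppressWarnings(as.integer(fields[3]))
      if (is.na(cl)) {
        ct_parse_error(sprintf("line %d: non-integer cluster ID '%s'", i, fields[3]),
                       line = i)
      }
      species <- c(species, fields[1]); gene <- c(gene, fields[2])
      clus <- c(clus, cl)
    } else {
      if (length(fields) < 2L) {
        ct_parse_error(sprintf("line %d: expected cluster ID plus >=1 member", i),
                       line = i)
      }
      cl <- suppressWarnings(as.integer(fields[1]))
      if (is.na(cl)) {
        ct_parse_error(sprintf("line %d: non-integer cluster ID '%s'", i, fields[1]),
                       line = i)
      }
      for (member in fields[-1]) {
        parts <- strsplit(member, "|", fixed = TRUE)[[1]]
        if (length(parts) != 2L) {
          ct_parse_error(sprintf("line %d: member '%s' is not species|gene", i, member),
                         line = i)
        }
        species <- c(species, parts[1]); gene <- c(gene, parts[2])
        clus <- c(clus, cl)
      }
    }
  }
  HomologyMap(species, gene, clus)
}

#' Attach homology clusters to a Genome
#'
#' Fills the `cluster` column of the feature table from a [HomologyMap];
#' genes absent from the map keep `NA`.
#'
#' @param genome A [Genome].
#' @param hmap A [HomologyMap], or `NULL` (no-op).
#' @return The updated [Genome].
#' @export
assign_homology <- function(genome, hmap) {
  if (is.null(hmap)) return(genome)
  genome$features$cluster <- homology_lookup(hmap, genome$species_name,
                                             genome$features$gene_id)
  genome
}

#' Parse custom context groupings from file
#'
#' Three-column tab-delimited rows: species, grouping label, gene_id. Each
#' `(species, label)` pair becomes one [ContextGrouping] with its genes in
#' genomic position order regardless of row order.
#'
#' @param path Path to the groupings file.
#' @param genomes Named list of [Genome] objects (names = species).
#' @return List of [ContextGrouping] objects in first-appearance order.
#' @export
parse_custom_groupings <- function(path, genomes) {
  if (!file.exists(path)) {
    ct_input_error(paste0("groupings file not found: ", path))
  }
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, function(g) g$species_name, character(1))
  }
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  rows <- list()
  for (i in idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      ct_parse_error(sprintf("line %d: expected 3 columns (species, label, gene)", i),
                     line = i)
    }
    sp <- fields[1]
    if (!sp %in% names(genomes)) {
      ct_input_error(sprintf("line %d: unknown species '%s'", i, sp))
    }
    g <- genomes[[sp]]
    if (!fields[3] %in% g$features$gene_id) {
      ct_input_error(sprintf("line %d: gene '%s' not present in genome '%s'",
                             i, fields[3], sp))
    }
    rows[[length(rows) + 1L]] <- fields
  }
  if (length(rows) == 0L) return(list())
  tab <- do.call(rbind, rows)
  keys <- paste(tab[, 1], tab[, 2], sep = "\t")
  out <- list()
  for (k in unique(keys)) {
    sel <- keys == k
    sp <- tab[sel, 1][1]
    label <- tab[sel, 2][1]
    g <- genomes[[sp]]
    feats <- g$features[g$features$gene_id %in% tab[sel, 3], , drop = FALSE]
    if (length(unique(feats$contig)) > 1L) {
      ct_input_error(sprintf("grouping '%s' of species '%s' spans multiple contigs",
                             label, sp))
    }
    out[[length(out) + 1L]] <- ContextGrouping(sp, feats, leaf_name = label)
  }
  out
}

#' Read a directory of GFF files as a genome working set
#'
#' Every `*.gff`/`*.gff3` file in `dir` becomes one Genome; the species
#' name is the file name without extension. Files are taken in sorted
#' order for determinism.
#'
#' @param dir Directory containing GFF files.
#' @param retain_types Passed to [parse_gff()].
#' @return Named list of [Genome] objects.
#' @export
read_genome_dir <- function(dir, retain_types = c("gene", "CDS")) {
  if (!dir.exists(dir)) ct_input_error(paste0("directory not found: ", dir))
  paths <- sort(list.files(dir, pattern = "\\.gff3?$", full.names = TRUE))
  if (length(paths) == 0L) ct_input_error(paste0("no .gff files in ", dir))
  species <- sub("\\.gff3?$", "", basename(paths))
  genomes <- Map(parse_gff, paths, species,
                 MoreArgs = list(retain_types = retain_types))
  stats::setNames(genomes, species)
}

#' Read genomes listed in a species mapping file
#'
#' @param path Path to a two-column mapping file (see
#'   [parse_species_mapping()]); relative GFF paths resolve against the
#'   mapping file's directory.
#' @param retain_types Passed to [parse_gff()].
#' @return Named list of [Genome] objects in file order.
#' @export
read_genome_mapping <- function(path, retain_types = c("gene", "CDS")) {
  mp <- parse_species_mapping(path)
  base <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  genomes <- Map(function(sp, p) parse_gff(resolve(p), sp, retain_types),
                 mp$species_name, mp$gff_path)
  stats::setNames(genomes, mp$species_name)
}
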