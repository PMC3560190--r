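# Synthetic genomes, homology maps and known-answer scenarios.
#
# Every scenario is fully determined by its seed and writes the same GFF
# and TSV dialects the readers consume, so the whole pipeline can be
# exercised from files on disk without any external data. The
# single_gene_vs_operon scenario reproduces the contrast that motivates
# context trees: a query gene that occurs either alone or inside a
# conserved 4-gene same-strand operon, depending on the species.

QUERY_CLUSTER <- 1L        # homology cluster of the planted query gene
OPERON_CLUSTERS <- 1:4     # clusters of the planted operon run
OPERON_GAPS <- c(12L, 8L, 15L)  # intra-operon gaps, all <= 20 nt

#' Specify a synthetic scenario
#'
#' @param scenario One of `"conserved_operon"` (the query operon is
#'   identical in every species), `"single_gene_vs_operon"` (half the
#'   species carry the query gene alone, half inside a 4-gene operon),
#'   `"gap_variation"` (same operon gene content and order everywhere,
#'   species-specific intergenic gaps), `"tie_block"` (each species' query
#'   context shares the query gene and adds one species-unique gene, so
#'   all pairwise Dice dissimilarities are equal).
#' @param n_species Number of genomes to generate (`>= 1`).
#' @param genes_per_genome Total genes per genome (`>= 5`; the planted
#'   context uses up to 4, the rest is background).
#' @param seed Integer seed; generation is fully determined by it.
#' @return An object of class `ScenarioSpec`.
#' @export
scenario_spec <- function(scenario = c("conserved_operon",
                                       "single_gene_vs_operon",
                                       "gap_variation", "tie_block"),
                          n_species = 6L, genes_per_genome = 12L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_species < 1L || genes_per_genome < 5L) {
    ct_usage_error("need n_species >= 1 and genes_per_genome >= 5")
  }
  structure(list(scenario = scenario, n_species = as.integer(n_species),
                 genes_per_genome = as.integer(genes_per_genome),
                 seed = as.integer(seed)),
            class = "ScenarioSpec")
}

# one synthetic genome: a planted context block followed by background
# genes; gene lengths uniform in [300, 1500] nt (plausible microbial
# scale), background gaps uniform in [200, 500] nt so background genes
# never chain with the planted block at thresholds <= 75 nt
synth_genome <- function(species, planted, genes_per_genome, unique_base) {
  glen <- function(n) sample(300:1500, n, replace = TRUE)
  n_bg <- genes_per_genome - nrow(planted)
  pos <- max(planted$end) + sample(200:500, 1L)
  bg <- list()
  for (i in seq_len(n_bg)) {
    len <- glen(1L)
    bg[[i]] <- data.frame(
      gene_id = sprintf("bg%02d", i), contig = "c1",
      start = pos, end = pos + len - 1L,
      strand = sample(c("+", "-"), 1L),
      annotation = sprintf("hypothetical protein %d", i),
      cluster = unique_base + i,
      stringsAsFactors = FALSE)
    pos <- pos + len + sample(200:500, 1L)
  }
  feats <- rbind(planted, do.call(rbind, bg))
  Genome(species, feats)
}

# the planted query block for one species; `type` decides its shape
planted_block <- function(type, gaps = OPERON_GAPS) {
  ann <- c("gamma-glutamyl transpeptidase homolog", "operon partner X",
           "operon partner Y", "operon partner Z")
  if (type == "single") {
    len <- sample(300:1500, 1L)
    return(data.frame(gene_id = "q1", contig = "c1", start = 1000L,
                      end = 1000L + len - 1L, strand = "+",
                      annotation = ann[1], cluster = QUERY_CLUSTER,
                      stringsAsFactors = FALSE))
  }
  lens <- sample(300:1500, 4L, replace = TRUE)
  start <- 1000L
  rows <- list()
  for (i in 1:4) {
    rows[[i]] <- data.frame(
      gene_id = if (i == 1L) "q1" else sprintf("op%d", i),
      contig = "c1", start = start, end = start + lens[i] - 1L,
      strand = "+", annotation = ann[i], cluster = OPERON_CLUSTERS[i],
      stringsAsFactors = FALSE)
    start <- start + lens[i] + (if (i < 4L) gaps[i] else 0L)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic known-answer scenario
#'
#' Builds `n_species` genomes with a planted query context per the
#' scenario, writes them as GFF files plus a long-format homology table
#' and a species mapping file under `dir`, and returns the in-memory
#' objects together with the ground truth the planted structure implies.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `genomes` (named list of [Genome]), `homology`
#'   ([HomologyMap]), `expected` (scenario ground truth: per-species
#'   planted type and the query cluster ID), and the written file paths
#'   (`mapping`, `homology_table`, `gff`).
#' @export
generate_scenario <- function(spec, dir = tempfile("scenario")) {
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- sprintf("species_%02d", seq_len(spec$n_species))
  types <- switch(spec$scenario,
    conserved_operon = rep("operon", spec$n_species),
    single_gene_vs_operon = rep(c("single", "operon"),
                                length.out = spec$n_species),
    gap_variation = rep("operon", spec$n_species),
    tie_block = rep("pair", spec$n_species))

  genomes <- list()
  for (i in seq_along(species)) {
    planted <- switch(types[i],
      single = planted_block("single"),
      operon = {
        gaps <- if (spec$scenario == "gap_variation") {
          sample(0:20, 3L, replace = TRUE)
        } else OPERON_GAPS
        planted_block("operon", gaps = gaps)
      },
      pair = {
        # query gene plus one species-unique partner 10 nt away
        base <- planted_block("single")
        len <- sample(300:1500, 1L)
        partner <- data.frame(gene_id = "u1", contig = "c1",
                              start = base$end + 11L,
                              end = base$end + 10L + len,
                              strand = "+",
                              annotation = sprintf("unique partner of %s",
                                                   species[i]),
                              cluster = 500L + i,
                              stringsAsFactors = FALSE)
        rbind(base, partner)
      })
    genomes[[species[i]]] <- synth_genome(species[i], planted,
                                          spec$genes_per_genome,
                                          unique_base = 1000L + i * 100L)
  }

  gff_paths <- character(0)
  for (sp in species) {
    p <- file.path(dir, paste0(sp, ".gff"))
    write_gff(genomes[[sp]], p)
    gff_paths <- c(gff_paths, p)
  }
  map_path <- file.path(dir, "species_mapping.tsv")
  writeLines(paste(species, paste0(species, ".gff"), sep = "\t"), map_path)

  hom_rows <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    data.frame(species = g$species_name, gene = f$gene_id,
               cluster = f$cluster, stringsAsFactors = FALSE)
  }))
  hom_path <- file.path(dir, "homology.tsv")
  writeLines(paste(hom_rows$species, hom_rows$gene, hom_rows$cluster,
                   sep = "\t"), hom_path)

  list(genomes = genomes,
       homology = HomologyMap(hom_rows$species, hom_rows$gene,
                              hom_rows$cluster),
       expected = list(types = stats::setNames(types, species),
                       query_cluster = QUERY_CLUSTER),
       mapping = map_path, homology_table = hom_path, gff = gff_paths,
       dir = dir)
}

#' Generate a fully tied dissimilarity matrix
#'
#' A `k x k` matrix with every off-diagonal equal to `d`: the canonical
#' input for exercising multidendrogram tie semantics (clustering it must
#' give a single k-child root).
#'
#' @param k Number of leaves (`>= 2`).
#' @param d Common dissimilarity (`> 0`).
#' @return A symmetric matrix with leaf names `T1..Tk`, class
#'   `DissimilarityMatrix`.
#' @export
generate_tie_block <- function(k, d = 1.0) {
  if (k < 2L || d <= 0) ct_usage_error("need k >= 2 and d > 0")
  m <- matrix(d, k, k)
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("T", seq_len(k))
  structure(m, metric = "synthetic", comparison_key = "none",
            class = c("DissimilarityMatrix", class(m)))
}
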