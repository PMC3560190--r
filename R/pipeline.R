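# End-to-end pipeline driver: parse -> group -> query -> metric ->
# cluster -> export. This is the programmatic surface behind the
# command-line script in inst/cli/.

# exit codes shared with the CLI wrapper
CT_EXIT <- c(ok = 0L, usage = 2L, input = 3L, parse = 4L, no_matches = 5L)

#' Assemble and validate a pipeline run configuration
#'
#' Collects every knob of a context-tree build. Mutually required fields
#' are validated up front: a homology-cluster query needs a homology
#' table, and exactly one of `genome_dir` / `mapping_file` must name the
#' genomes.
#'
#' @param genome_dir Directory of per-species GFF files, or `NULL`.
#' @param mapping_file Two-column species mapping file, or `NULL`.
#' @param homology_file Homology-cluster table, or `NULL`.
#' @param homology_format Layout of `homology_file` (see
#'   [parse_homology_table()]).
#' @param query_mode,query_value,case_sensitive The search query (see
#'   [context_query()]).
#' @param context_scheme,threshold,distance,k,window The context set (see
#'   [context_set()]); `context_name` labels it (e.g. `"D75"`).
#' @param context_name Context-set display name.
#' @param metric,comparison_key,penalty,cap,mirror Dissimilarity settings
#'   (see [build_matrix()]).
#' @param linkage,tie_epsilon Linkage settings (see [linkage_spec()]).
#' @param height_mode Newick node heights (see [to_newick()]).
#' @param newick_out,matrix_out,matrix_format,svg_out Output paths;
#'   `NULL` skips that artifact.
#' @param render_opts A [render_options()].
#' @param legend Draw the SVG color legend.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(genome_dir = NULL, mapping_file = NULL,
                       homology_file = NULL, homology_format = "long",
                       query_mode = "homology_cluster_id", query_value,
                       case_sensitive = FALSE,
                       context_scheme = "strand_distance",
                       context_name = NULL,
                       threshold = 20L, distance = 75L, k = 1L, window = 0L,
                       metric = "dice", comparison_key = "homology_cluster",
                       penalty = 0, cap = 10000, mirror = TRUE,
                       linkage = "joint_between_within", tie_epsilon = 1e-9,
                       height_mode = "band_low",
                       newick_out = NULL, matrix_out = NULL,
                       matrix_format = "phylip", svg_out = NULL,
                       render_opts = render_options(), legend = FALSE) {
  if (is.null(genome_dir) == is.null(mapping_file)) {
    ct_usage_error("exactly one of genome_dir / mapping_file is required")
  }
  if (query_mode == "homology_cluster_id" && is.null(homology_file)) {
    ct_usage_error("a homology-cluster query requires a homology table")
  }
  if (is.null(context_name)) {
    context_name <- if (context_scheme == "strand_distance") {
      paste0("D", distance)
    } else context_scheme
  }
  structure(list(
    genome_dir = genome_dir, mapping_file = mapping_file,
    homology_file = homology_file, homology_format = homology_format,
    query = context_query(query_mode, query_value, case_sensitive),
    cs = context_set(context_name, context_scheme, threshold = threshold,
                     distance = distance, k = k, window = window),
    metric = metric, comparison_key = comparison_key,
    penalty = penalty, cap = cap, mirror = mirror,
    link = linkage_spec(linkage, tie_epsilon),
    height_mode = height_mode,
    newick_out = newick_out, matrix_out = matrix_out,
    matrix_format = matrix_format, svg_out = svg_out,
    render_opts = render_opts, legend = legend),
    class = "RunConfig")
}

ct_log <- function(...) message("[contexttrees] ", sprintf(...))

load_working_set <- function(cfg) {
  genomes <- if (!is.null(cfg$mapping_file)) {
    read_genome_mapping(cfg$mapping_file)
  } else {
    read_genome_dir(cfg$genome_dir)
  }
  hmap <- NULL
  if (!is.null(cfg$homology_file)) {
    hmap <- parse_homology_table(cfg$homology_file, cfg$homology_format)
    genomes <- lapply(genomes, assign_homology, hmap = hmap)
  }
  list(genomes = genomes, hmap = hmap)
}

#' Run the full context-tree pipeline
#'
#' Loads the genome working set and homology table, runs the query,
#' builds context leaves under the configured scheme, computes the
#' dissimilarity matrix, clusters it into a multidendrogram, and writes
#' the configured artifacts. Progress goes to `stderr` via `message()`;
#' results only to files.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `status` (0 on success, the `no_matches`
#'   code when the query hits nothing), `leaves`, `matrix`, `tree`, and
#'   the genome working set. On a no-match query no output file is
#'   written.
#' @export
run_build_tree <- function(cfg) {
  ws <- load_working_set(cfg)
  ct_log("loaded %d genome(s)", length(ws$genomes))
  leaves <- build_context_leaves(ws$genomes, ws$hmap, cfg$query, cfg$cs)
  if (length(leaves) == 0L) {
    ct_log("query matched nothing; no outputs written")
    return(invisible(list(status = CT_EXIT[["no_matches"]],
                          leaves = list(), matrix = NULL, tree = NULL,
                          genomes = ws$genomes, hmap = ws$hmap)))
  }
  ct_log("context set '%s': %d leaves", cfg$cs$name, length(leaves))
  M <- build_matrix(leaves, metric = cfg$metric, key = cfg$comparison_key,
                    penalty = cfg$penalty, cap = cfg$cap, mirror = cfg$mirror)
  tree <- cluster_multidendrogram(M, cfg$link)
  ct_log("metric=%s key=%s linkage=%s", cfg$metric, cfg$comparison_key,
         cfg$link$method)
  if (!is.null(cfg$newick_out)) write_newick(tree, cfg$newick_out,
                                             cfg$height_mode)
  if (!is.null(cfg$matrix_out)) write_matrix(M, cfg$matrix_out,
                                             cfg$matrix_format)
  invisible(list(status = CT_EXIT[["ok"]], leaves = leaves, matrix = M,
                 tree = tree, genomes = ws$genomes, hmap = ws$hmap))
}

#' Render the contexts of a built tree as SVG
#'
#' Renders the leaves passing a name filter (viewer search-bar
#' semantics; empty filter = all leaves) from a [run_build_tree()]
#' result. A filter matching nothing produces a warning and no file.
#'
#' @param cfg The [run_config()] used for the build (supplies render
#'   options and the SVG path).
#' @param build The list returned by [run_build_tree()]; when `NULL` the
#'   build is executed first.
#' @param leaf_filter Substring filter on leaf names.
#' @return Invisibly, a list with `status` and `svg` (the path, or `NULL`).
#' @export
run_render <- function(cfg, build = NULL, leaf_filter = "") {
  if (is.null(build)) build <- run_build_tree(cfg)
  if (build$status != CT_EXIT[["ok"]]) {
    return(invisible(list(status = build$status, svg = NULL)))
  }
  wanted <- select_leaves(build$tree, leaf_filter)
  leaves <- Filter(function(l) l$leaf_name %in% wanted, build$leaves)
  if (length(leaves) == 0L) {
    warning("leaf filter '", leaf_filter, "' matched no leaves; no SVG written")
    return(invisible(list(status = CT_EXIT[["ok"]], svg = NULL)))
  }
  colors <- color_assignment(leaves, cfg$comparison_key)
  layouts <- lapply(leaves, function(l) {
    layout_context(l, build$genomes[[l$species_name]], cfg$render_opts)
  })
  out <- cfg$svg_out
  if (is.null(out)) out <- tempfile(fileext = ".svg")
  render_svg(layouts, colors, key = cfg$comparison_key, out_path = out,
             legend = cfg$legend, opts = cfg$render_opts)
  ct_log("rendered %d context(s) to %s", length(layouts), out)
  invisible(list(status = CT_EXIT[["ok"]], svg = out))
}

#' Map a caught pipeline error to a CLI exit code
#'
#' @param cond A condition object.
#' @return Integer exit code (usage 2, input 3, parse 4; 1 otherwise).
#' @export
exit_code_for <- function(cond) {
  if (inherits(cond, "ct_usage_error")) return(CT_EXIT[["usage"]])
  if (inherits(cond, "ct_input_error")) return(CT_EXIT[["input"]])
  if (inherits(cond, "ct_parse_error")) return(CT_EXIT[["parse"]])
  1L
}
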