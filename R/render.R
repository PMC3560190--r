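# SVG rendering of genomic contexts: the multi-genome browser view.
# Genes draw as rectangles above (+ strand) or below (- strand) a
# centerline; panels stack in leaf order; colors follow identity keys.

# layout constants (pixels); documented, deliberately plain
PANEL_WIDTH <- 900
PANEL_HEIGHT <- 80
PANEL_PAD <- 14
GENE_HEIGHT <- 22
LEGEND_ROW <- 18
FLANK_GRAY <- "#BEBEBE"

#' Rendering options for context diagrams
#'
#' Mirrors the viewer's display checkboxes: show genomic coordinates,
#' normalize contexts by strand, show the genes surrounding a context,
#' and color (vs gray out) those surrounding genes; `flank_nt` sets the
#' displayed range around the context segment.
#'
#' @param show_coordinates Draw a coordinate caption per panel.
#' @param normalize_strand Mirror contexts whose genes are predominantly
#'   on the minus strand.
#' @param show_surrounding Include genes within `flank_nt` of the span.
#' @param color_surrounding Color surrounding genes by identity key
#'   instead of gray.
#' @param flank_nt Nucleotides of flank to display each side (`>= 0`).
#' @return An object of class `RenderOptions`.
#' @export
render_options <- function(show_coordinates = FALSE, normalize_strand = FALSE,
                           show_surrounding = FALSE, color_surrounding = FALSE,
                           flank_nt = 0L) {
  if (flank_nt < 0L) ct_usage_error("flank_nt must be >= 0")
  structure(list(show_coordinates = isTRUE(show_coordinates),
                 normalize_strand = isTRUE(normalize_strand),
                 show_surrounding = isTRUE(show_surrounding),
                 color_surrounding = isTRUE(color_surrounding),
                 flank_nt = as.integer(flank_nt)),
            class = "RenderOptions")
}

#' Compute the glyph layout of one context
#'
#' Positions every gene of the grouping (and, with `show_surrounding`,
#' the genes within `flank_nt` of its span) in nucleotide coordinates
#' relative to the context midpoint: the viewport center maps to
#' `(span_start + span_end) / 2`. With `normalize_strand`, a context
#' whose genes are mostly minus-strand mirrors about that midpoint and
#' flips strands, so applying the mirror twice restores the original.
#'
#' @param grouping A [ContextGrouping].
#' @param genome The [Genome] it came from (needed for surrounding genes).
#' @param opts A [render_options()].
#' @return Data frame of glyphs with columns `gene_id`, `key_cluster`,
#'   `key_annotation`, `x0`, `x1` (nt offsets from midpoint), `above`
#'   (logical: forward strand), `role` (`"context"`/`"flank"`); class
#'   `context_layout` with the grouping's name and span as attributes.
#' @export
layout_context <- function(grouping, genome, opts = render_options()) {
  if (!identical(grouping$species_name, genome$species_name)) {
    ct_usage_error("grouping does not belong to this genome")
  }
  f <- genome$features
  in_ctx <- f$gene_id %in% grouping$genes$gene_id
  if (!all(grouping$genes$gene_id %in% f$gene_id)) {
    ct_usage_error("grouping genes missing from genome")
  }
  rows <- which(in_ctx & f$contig == grouping$contig)
  role <- rep("context", length(rows))
  if (opts$show_surrounding) {
    lo <- grouping$span_start - opts$flank_nt
    hi <- grouping$span_end + opts$flank_nt
    fl <- which(!in_ctx & f$contig == grouping$contig &
                f$start <= hi & f$end >= lo)
    rows <- c(rows, fl)
    role <- c(role, rep("flank", length(fl)))
  }
  mid <- (grouping$span_start + grouping$span_end) / 2
  x0 <- f$start[rows] - mid
  x1 <- f$end[rows] - mid
  above <- f$strand[rows] == "+"
  if (opts$normalize_strand) {
    ctx_strands <- grouping$genes$strand
    if (sum(ctx_strands == "-") * 2L > length(ctx_strands)) {
      tmp <- x0
      x0 <- -x1
      x1 <- -tmp
      above <- !above
    }
  }
  out <- data.frame(gene_id = f$gene_id[rows],
                    key_cluster = as.character(f$cluster[rows]),
                    key_annotation = normalize_annotation(f$annotation[rows]),
                    x0 = x0, x1 = x1, above = above, role = role,
                    stringsAsFactors = FALSE)
  out <- out[order(out$x0, out$x1, out$gene_id, method = "radix"), ]
  rownames(out) <- NULL
  structure(out, class = c("context_layout", class(out)),
            leaf_name = grouping$leaf_name,
            span = c(grouping$span_start, grouping$span_end),
            contig = grouping$contig)
}

#' Assign colors to identity keys
#'
#' Every identity key appearing in the context genes of the given leaves
#' receives one color; identical keys share a color across all contexts,
#' and distinct keys get maximally spaced hues on an HSV wheel in sorted
#' key order, so the map is deterministic. Gray is reserved for
#' surrounding genes and never assigned.
#'
#' @param leaves List of [ContextGrouping] objects.
#' @param key `"homology_cluster"` or `"annotation"`.
#' @return Named character vector: key -> hex color.
#' @export
color_assignment <- function(leaves, key = c("homology_cluster", "annotation")) {
  key <- match.arg(key)
  keys <- sort(unique(unlist(lapply(leaves, identity_keys, key = key))))
  n <- length(keys)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  cols <- grDevices::hsv(h = (seq_len(n) - 1) / n, s = 0.62, v = 0.86)
  stats::setNames(cols, keys)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

svg_num <- function(x) sub("\\.$", "", sub("0+$", "", sprintf("%.3f", x)))

#' Render context layouts to an SVG file
#'
#' One stacked panel per layout, top to bottom in the given order; each
#' panel draws its centerline, gene rectangles above/below it, the leaf
#' name, and optionally a coordinate caption. All panels share one
#' nucleotide-to-pixel scale so spacing is comparable across contexts.
#' Output is deterministic: identical inputs give a byte-identical file.
#'
#' @param layouts List of [layout_context()] results.
#' @param colors Named color map from [color_assignment()].
#' @param key Which identity key the colors index.
#' @param out_path Output file path.
#' @param legend Append an alphabetized color legend.
#' @param opts A [render_options()] (coordinate captions, gray flanks).
#' @return `out_path`, invisibly.
#' @export
render_svg <- function(layouts, colors, key = c("homology_cluster", "annotation"),
                       out_path, legend = FALSE, opts = render_options()) {
  key <- match.arg(key)
  if (length(layouts) == 0L) ct_usage_error("need >= 1 layout to render")
  half_extent <- max(vapply(layouts, function(l) max(abs(c(l$x0, l$x1, 1))),
                            numeric(1)))
  inner <- PANEL_WIDTH - 2 * PANEL_PAD
  scale <- inner / (2 * half_extent)       # px per nt, shared across panels
  px <- function(x) PANEL_WIDTH / 2 + x * scale

  n_legend <- if (legend) length(colors) else 0L
  height <- length(layouts) * PANEL_HEIGHT + n_legend * LEGEND_ROW +
    (if (legend) PANEL_PAD else 0L)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
            PANEL_WIDTH, height))
  for (i in seq_along(layouts)) {
    l <- layouts[[i]]
    y0 <- (i - 1) * PANEL_HEIGHT
    cy <- y0 + PANEL_HEIGHT / 2
    lines <- c(lines,
      sprintf('<g id="panel-%d">', i),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1"/>',
              svg_num(PANEL_PAD), svg_num(cy),
              svg_num(PANEL_WIDTH - PANEL_PAD), svg_num(cy)),
      sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif">%s</text>',
              svg_num(PANEL_PAD), svg_num(y0 + 12),
              xml_escape(attr(l, "leaf_name"))))
    if (opts$show_coordinates) {
      span <- attr(l, "span")
      lines <- c(lines,
        sprintf('<text x="%s" y="%s" font-size="9" font-family="sans-serif" fill="#666666">%s:%d-%d</text>',
                svg_num(PANEL_PAD), svg_num(y0 + PANEL_HEIGHT - 4),
                xml_escape(attr(l, "contig")), span[1], span[2]))
    }
    for (j in seq_len(nrow(l))) {
      keyval <- if (key == "homology_cluster") l$key_cluster[j] else l$key_annotation[j]
      fill <- if (l$role[j] == "flank" && !opts$color_surrounding) {
        FLANK_GRAY
      } else if (!is.na(keyval) && keyval %in% names(colors)) {
        unname(colors[keyval])
      } else {
        FLANK_GRAY
      }
      ry <- if (l$above[j]) cy - GENE_HEIGHT else cy
      lines <- c(lines,
        sprintf('<rect x="%s" y="%s" width="%s" height="%d" fill="%s" stroke="#222222" stroke-width="0.5"><title>%s</title></rect>',
                svg_num(px(l$x0[j])), svg_num(ry),
                svg_num(max((l$x1[j] - l$x0[j] + 1) * scale, 1)),
                GENE_HEIGHT, fill, xml_escape(l$gene_id[j])))
    }
    lines <- c(lines, "</g>")
  }
  if (legend && length(colors) > 0L) {
    # alphabetized legend
    ord <- order(names(colors), method = "radix")
    y0 <- length(layouts) * PANEL_HEIGHT + PANEL_PAD
    lines <- c(lines, '<g id="legend">')
    for (k in seq_along(ord)) {
      nm <- names(colors)[ord[k]]
      y <- y0 + (k - 1) * LEGEND_ROW
      lines <- c(lines,
        sprintf('<rect x="%s" y="%s" width="12" height="12" fill="%s"/>',
                svg_num(PANEL_PAD), svg_num(y), unname(colors[ord[k]])),
        sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif">%s</text>',
                svg_num(PANEL_PAD + 18), svg_num(y + 10), xml_escape(nm)))
    }
    lines <- c(lines, "</g>")
  }
  lines <- c(lines, "</svg>")
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(out_path)
}
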