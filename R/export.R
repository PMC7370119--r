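# Deterministic graph exporters: DOT, Newick, node-link JSON.

# fixed 9-entry palette keyed by stage index (stage 0 roots are grey)
STAGE_COLORS <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
                  "#e6ab02", "#a6761d", "#666666", "#e41a1c")
ROOT_COLOR <- "#999999"

#' Exporter configuration
#'
#' @param color_by_stage color node borders by stage (9 fixed colors).
#' @param include_cross_talk emit cross-talk edges (dashed) in DOT/JSON.
#' @param base_filter optional subset of `c("A","C","G","U")` restricting
#'   the export to those trees.
#' @param label node labelling: `"short_name"`, `"full_name"`, or
#'   `"both"`.
#' @return An `export_config` list.
#' @export
export_config <- function(color_by_stage = TRUE, include_cross_talk = FALSE,
                          base_filter = NULL, label = c("short_name", "full_name", "both")) {
  label <- match.arg(label)
  if (!is.null(base_filter)) {
    bad <- setdiff(base_filter, ROOT_BASES)
    if (length(bad) > 0L) stop("unknown base '", bad[1L], "'")
  }
  structure(list(color_by_stage = isTRUE(color_by_stage),
                 include_cross_talk = isTRUE(include_cross_talk),
                 base_filter = base_filter,
                 label = label), class = "export_config")
}

forest_subset <- function(forest, config) {
  bases <- if (is.null(config$base_filter)) ROOT_BASES
           else intersect(ROOT_BASES, config$base_filter)
  nodes <- forest$nodes[forest$root_of[forest$nodes] %in% bases]
  list(bases = bases, nodes = nodes)
}

dot_escape <- function(x) gsub('"', '\\\\"', x)

node_label <- function(forest, nm, label) {
  full <- forest$records$full_name[match(nm, forest$records$short_name)]
  switch(label,
         short_name = nm,
         full_name = if (is.na(full) || !nzchar(full)) nm else full,
         both = if (is.na(full) || !nzchar(full)) nm
                else paste0(nm, "\\n", full))
}

#' Export the forest as a DOT digraph
#'
#' One `digraph`, nodes in sorted order (roots first), each placed node
#' carrying a `stage` attribute and a stage-indexed border color; tree
#' edges are solid, cross-talk edges dashed when included.  Output is
#' byte-stable for identical inputs.
#'
#' @param forest a `mod_forest`.
#' @param config an [export_config()].
#' @return A single character string of DOT text.
#' @export
to_dot <- function(forest, config = export_config()) {
  stopifnot(inherits(forest, "mod_forest"))
  sub <- forest_subset(forest, config)
  lines <- c("digraph modification_forest {",
             "  rankdir=TB;",
             "  node [shape=box, style=rounded];")
  for (b in sub$bases)
    lines <- c(lines, sprintf(
      '  "%s" [label="%s", stage=0, color="%s"];', b, b, ROOT_COLOR))
  for (nm in sub$nodes) {
    st <- forest$stage[[nm]]
    col <- if (config$color_by_stage) STAGE_COLORS[st] else "black"
    lines <- c(lines, sprintf(
      '  "%s" [label="%s", stage=%d, color="%s"];',
      dot_escape(nm), dot_escape(node_label(forest, nm, config$label)), st, col))
  }
  for (nm in sub$nodes)
    lines <- c(lines, sprintf('  "%s" -> "%s";',
                              dot_escape(forest$parent[[nm]]), dot_escape(nm)))
  if (config$include_cross_talk && nrow(forest$cross_talk) > 0L) {
    ct <- forest$cross_talk
    present <- c(sub$bases, sub$nodes)
    for (i in seq_len(nrow(ct))) {
      if (ct$source[i] %in% present && ct$target[i] %in% present)
        lines <- c(lines, sprintf(
          '  "%s" -> "%s" [style=dashed, label="%s"];',
          dot_escape(ct$source[i]), dot_escape(ct$target[i]),
          dot_escape(ct$kind[i])))
    }
  }
  paste(c(lines, "}", ""), collapse = "\n")
}

# quote a Newick label when it contains characters with grammar meaning
newick_quote <- function(x) {
  if (grepl("[](),:;'\\[ \t]", x))
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  else x
}

#' Export one tree as a Newick string
#'
#' Rooted, internal nodes labeled, children in sorted order, no branch
#' lengths.  Labels containing commas, parentheses, colons or quotes
#' (e.g. `m2,2G`) are single-quoted with internal quotes doubled, per the
#' Newick standard.
#'
#' @param forest a `mod_forest`.
#' @param base one of A, C, G, U.
#' @return A Newick string ending in `";"`.
#' @export
to_newick <- function(forest, base) {
  stopifnot(inherits(forest, "mod_forest"))
  if (!base %in% ROOT_BASES) stop("unknown base '", base, "'")
  nwk <- function(nm) {
    ch <- forest$children[[nm]]
    lab <- newick_quote(nm)
    if (length(ch) == 0L) lab
    else paste0("(", paste(vapply(ch, nwk, ""), collapse = ","), ")", lab)
  }
  paste0(nwk(base), ";")
}

#' Export the forest as node-link JSON
#'
#' `{"nodes": [{id, stage, root_base, status, full_name}, ...],
#'   "links": [{source, target, kind}, ...]}` with deterministic
#' ordering: the four roots first, then placed nodes sorted by name;
#' tree links sorted by target, cross-talk links appended when included.
#'
#' @param forest a `mod_forest`.
#' @param config an [export_config()].
#' @return JSON text.
#' @export
to_json_graph <- function(forest, config = export_config(include_cross_talk = TRUE)) {
  stopifnot(inherits(forest, "mod_forest"))
  sub <- forest_subset(forest, config)
  nodes <- c(
    lapply(sub$bases, function(b)
      list(id = b, stage = 0L, root_base = b, status = "root", full_name = b)),
    lapply(sub$nodes, function(nm) {
      i <- match(nm, forest$records$short_name)
      list(id = nm, stage = forest$stage[[nm]],
           root_base = forest$root_of[[nm]], status = "placed",
           full_name = forest$records$full_name[i])
    }))
  links <- lapply(sub$nodes, function(nm)
    list(source = forest$parent[[nm]], target = nm, kind = "parent"))
  if (config$include_cross_talk && nrow(forest$cross_talk) > 0L) {
    ct <- forest$cross_talk
    present <- c(sub$bases, sub$nodes)
    for (i in seq_len(nrow(ct)))
      if (ct$source[i] %in% present && ct$target[i] %in% present)
        links[[length(links) + 1L]] <- list(source = ct$source[i],
                                            target = ct$target[i],
                                            kind = ct$kind[i])
  }
  as.character(jsonlite::toJSON(list(nodes = nodes, links = links),
                                auto_unbox = TRUE, pretty = TRUE))
}
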