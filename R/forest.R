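# The rooted modification forest and its stage statistics.
#
# The four natural ribonucleosides are virtual stage-0 roots; every placed
# record hangs below exactly one of them, and an edge is one chemical
# modification, so stage(child) = stage(parent) + 1.

MAX_STAGE <- 9L

#' Cross-talk edges between trees
#'
#' Non-tree relations connecting cytidine- and uridine-derived marks:
#' enzymatic deamination converts C to U, and m3C can be converted
#' directly to m3U.  These edges never take part in stage computation,
#' descendant sets, or counts; exporters render them dashed.
#'
#' @return data.frame with columns `source`, `target`, `kind`.
#' @export
cross_talk_edges <- function() {
  data.frame(source = c("C", "m3C"),
             target = c("U", "m3U"),
             kind = c("deamination C->U", "deamination m3C->m3U"))
}

#' Build the modification forest
#'
#' Assembles the rooted forest over the placed records of a census.
#' Records with no explicit parent attach to their root base at stage 1;
#' all others attach to their curated parent.  Children lists are sorted
#' by short name so every downstream export is deterministic.  Unplaced
#' and nascent records are excluded.
#'
#' @param census a valid `mod_census`.
#' @param cross_talk data.frame of cross-tree edges (`source`, `target`,
#'   `kind`); edges whose endpoints are absent from the forest are dropped.
#' @return A `mod_forest`: list with `roots`, `nodes`, `parent`,
#'   `children`, `stage`, `root_of`, `records`, `cross_talk`.
#' @export
build_forest <- function(census, cross_talk = cross_talk_edges()) {
  stopifnot(inherits(census, "mod_census"))
  report <- validate_census(census)
  if (!report$ok)
    stop("census is invalid (", nrow(report$violations),
         " violation(s)); run validate_census() for the report")
  rec <- census$records
  placed <- rec[rec$status == "placed", , drop = FALSE]
  nodes <- placed$short_name

  parent <- ifelse(nzchar(placed$parent), placed$parent, placed$root_base)
  names(parent) <- nodes
  bad_root <- nodes[!(parent %in% c(nodes, ROOT_BASES))]
  if (length(bad_root) > 0L)
    stop("unresolvable parent for: ", paste(bad_root, collapse = ", "))

  # cycle detection by parent walk
  for (nm in nodes) {
    seen <- character(0)
    cur <- nm
    while (!cur %in% ROOT_BASES) {
      if (cur %in% seen) {
        cyc <- seen[which(seen == cur):length(seen)]
        stop("cycle in parent links: ", paste(c(cyc, cur), collapse = " -> "))
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }

  # root-base agreement along every edge
  root_of_node <- setNames(placed$root_base, nodes)
  for (nm in nodes) {
    p <- parent[[nm]]
    proot <- if (p %in% ROOT_BASES) p else root_of_node[[p]]
    if (proot != root_of_node[[nm]])
      stop("parent '", p, "' of '", nm, "' belongs to the ", proot,
           " tree but the record is rooted at ", root_of_node[[nm]])
  }

  children <- lapply(setNames(nm = c(ROOT_BASES, nodes)), function(p)
    sort_names(nodes[parent == p]))

  stage <- setNames(rep(NA_integer_, length(nodes)), nodes)
  queue <- ROOT_BASES
  depth <- setNames(rep(0L, 4L), ROOT_BASES)
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (ch in children[[cur]]) {
      stage[[ch]] <- depth[[cur]] + 1L
      depth[[ch]] <- stage[[ch]]
      queue <- c(queue, ch)
    }
  }

  ct <- cross_talk
  if (!is.null(ct) && nrow(ct) > 0L) {
    present <- c(ROOT_BASES, nodes)
    ct <- ct[ct$source %in% present & ct$target %in% present, , drop = FALSE]
    rownames(ct) <- NULL
  } else {
    ct <- cross_talk_edges()[0, ]
  }

  structure(list(roots = ROOT_BASES,
                 nodes = sort_names(nodes),
                 parent = parent,
                 children = children,
                 stage = stage,
                 root_of = root_of_node,
                 records = placed,
                 census_status = setNames(rec$status, rec$short_name),
                 cross_talk = ct),
            class = "mod_forest")
}

# deterministic, locale-independent name ordering
sort_names <- function(x) x[order(method = "radix", x)]

#' Stage of a node
#'
#' Edge distance from the node's root base; the four roots are stage 0.
#'
#' @param forest a `mod_forest`.
#' @param name a placed short name or a root base.
#' @return Integer stage.
#' @export
compute_stage <- function(forest, name) {
  stopifnot(inherits(forest, "mod_forest"))
  if (name %in% forest$roots) return(0L)
  st <- forest$stage[name]
  if (is.na(st)) {
    if (name %in% names(forest$census_status))
      stop("'", name, "' is not placed")
    stop("unknown name '", name, "'")
  }
  unname(st)
}

#' Per-base, per-stage counts
#'
#' The machine twin of the paper-style summary grid: for each root base,
#' the number of placed derivatives at each stage 1..9, together with the
#' per-branch totals and the grand total.
#'
#' @param forest a `mod_forest`.
#' @return A `stage_matrix`: list with `counts` (9 x 4 integer matrix,
#'   rows = stages, columns = A,C,G,U), `branch_totals`, `grand_total`.
#' @export
stage_matrix <- function(forest) {
  stopifnot(inherits(forest, "mod_forest"))
  counts <- matrix(0L, nrow = MAX_STAGE, ncol = 4L,
                   dimnames = list(stage = as.character(1:MAX_STAGE),
                                   base = ROOT_BASES))
  for (nm in forest$nodes)
    counts[forest$stage[[nm]], forest$root_of[[nm]]] <-
      counts[forest$stage[[nm]], forest$root_of[[nm]]] + 1L
  branch_totals <- colSums(counts)
  structure(list(counts = counts,
                 branch_totals = branch_totals,
                 grand_total = sum(branch_totals)),
            class = "stage_matrix")
}

#' @export
print.stage_matrix <- function(x, ...) {
  m <- rbind(x$counts, total = x$branch_totals)
  print(m)
  cat("grand total:", x$grand_total, "\n")
  invisible(x)
}

#' Total number of marks in one tree
#' @param forest a `mod_forest`.
#' @param base one of A, C, G, U.
#' @return Integer node count of that tree (excluding the root).
#' @export
branch_total <- function(forest, base) {
  stopifnot(inherits(forest, "mod_forest"))
  if (!base %in% ROOT_BASES) stop("unknown base '", base, "'")
  sum(forest$root_of == base)
}

#' Height of one tree
#' @inheritParams branch_total
#' @return Maximum stage present in that tree (0 for an empty tree).
#' @export
tree_height <- function(forest, base) {
  stopifnot(inherits(forest, "mod_forest"))
  if (!base %in% ROOT_BASES) stop("unknown base '", base, "'")
  st <- forest$stage[forest$root_of == base]
  if (length(st) == 0L) 0L else max(st)
}

#' Range of first-stage counts across the four trees
#' @param forest a `mod_forest`.
#' @return Integer vector `c(min, max)` of stage-1 counts.
#' @export
first_stage_range <- function(forest) {
  s1 <- stage_matrix(forest)$counts["1", ]
  c(min = min(s1), max = max(s1))
}

#' All marks below a node
#'
#' The set of placed short names in the subtree rooted at `name`,
#' excluding `name` itself.  Cross-talk edges are never followed.
#'
#' @param forest a `mod_forest`.
#' @param name a placed short name or a root base.
#' @return Character vector, sorted.
#' @export
descendants <- function(forest, name) {
  stopifnot(inherits(forest, "mod_forest"))
  if (!name %in% c(forest$roots, forest$nodes)) stop("unknown name '", name, "'")
  out <- character(0)
  queue <- forest$children[[name]]
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    out <- c(out, cur)
    queue <- c(queue, forest$children[[cur]])
  }
  sort_names(out)
}

#' Lineage of a node
#'
#' @param forest a `mod_forest`.
#' @param name a placed short name.
#' @return Character vector `c(name, parent, ..., root)`.
#' @export
path_to_root <- function(forest, name) {
  stopifnot(inherits(forest, "mod_forest"))
  if (name %in% forest$roots) return(name)
  if (!name %in% forest$nodes) stop("unknown name '", name, "'")
  path <- name
  cur <- name
  while (!cur %in% forest$roots) {
    cur <- forest$parent[[cur]]
    path <- c(path, cur)
  }
  path
}

#' @export
print.mod_forest <- function(x, ...) {
  cat("modification forest:", length(x$nodes), "placed marks across 4 trees\n")
  sm <- stage_matrix(x)
  cat("  branch totals:",
      paste(sprintf("%s=%d", names(sm$branch_totals), sm$branch_totals),
            collapse = ", "), "\n")
  cat("  heights:",
      paste(sprintf("%s=%d", ROOT_BASES,
                    vapply(ROOT_BASES, function(b) tree_height(x, b), 0L)),
            collapse = ", "), "\n")
  if (nrow(x$cross_talk) > 0L)
    cat("  cross-talk edges:", nrow(x$cross_talk), "\n")
  invisible(x)
}

#' @export
summary.mod_forest <- function(object, ...) {
  print(stage_matrix(object))
  invisible(object)
}
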