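# Fixtures are built in code: small hand-written censuses and randomized
# synthetic ones for the structural properties.

PSI <- "Ψ"  # the Greek capital psi used in canonical short names

empty_record <- function() {
  cols <- rnamodcensus:::CENSUS_COLUMNS
  listcols <- rnamodcensus:::CENSUS_LIST_COLUMNS
  out <- setNames(vector("list", length(cols)), cols)
  for (col in cols)
    out[[col]] <- if (col %in% listcols) character(0) else ""
  out$reversible <- "unknown"
  out$status <- "placed"
  out
}

# build a census from partial record specs, e.g.
#   tiny_census(list(short_name = "m7G", root_base = "G"))
tiny_census <- function(..., version = "t", source_note = "") {
  specs <- list(...)
  rows <- lapply(specs, function(sp) {
    rec <- empty_record()
    rec[names(sp)] <- sp
    if (!nzchar(rec$ascii_alias)) rec$ascii_alias <- rec$short_name
    rec
  })
  cols <- rnamodcensus:::CENSUS_COLUMNS
  listcols <- rnamodcensus:::CENSUS_LIST_COLUMNS
  records <- data.frame(short_name = vapply(rows, `[[`, "", "short_name"))
  for (col in cols) {
    records[[col]] <- if (col %in% listcols) I(lapply(rows, `[[`, col))
                      else vapply(rows, function(r) as.character(r[[col]]), "")
  }
  as_census(records, version = version, source_note = source_note)
}

# random rooted forest over the four bases; names are synthetic
random_census <- function(seed, max_per_base = 12L) {
  set.seed(seed)
  specs <- list()
  for (base in c("A", "C", "G", "U")) {
    n <- sample.int(max_per_base + 1L, 1L) - 1L
    names_b <- if (n > 0L) paste0("x", base, seq_len(n)) else character(0)
    for (i in seq_len(n)) {
      parent <- if (i == 1L || stats::runif(1) < 0.3) ""
                else names_b[sample.int(i - 1L, 1L)]
      specs[[length(specs) + 1L]] <- list(short_name = names_b[i],
                                          root_base = base, parent = parent)
    }
  }
  if (length(specs) == 0L)
    specs <- list(list(short_name = "xA1", root_base = "A"))
  do.call(tiny_census, specs)
}

# independent breadth-first stage computation straight from census records
bfs_stages <- function(census) {
  rec <- census$records[census$records$status == "placed", ]
  parent <- ifelse(nzchar(rec$parent), rec$parent, rec$root_base)
  names(parent) <- rec$short_name
  depth <- c(A = 0L, C = 0L, G = 0L, U = 0L)
  repeat {
    nxt <- names(parent)[parent %in% names(depth) & !names(parent) %in% names(depth)]
    if (length(nxt) == 0L) break
    for (nm in nxt) depth[[nm]] <- depth[[parent[[nm]]]] + 1L
  }
  depth[setdiff(names(depth), c("A", "C", "G", "U"))]
}

# naive full-scan query oracle, written independently of query_census()
scan_oracle <- function(census, filter) {
  rec <- census$records
  hit <- logical(nrow(rec))
  strip_qual <- function(x) sub("\\[[a-z]+\\]$", "", x)
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    if (!is.null(filter$kingdom))
      ok <- ok && filter$kingdom %in% rec$kingdoms[[i]]
    if (!is.null(filter$rna_class))
      ok <- ok && filter$rna_class %in% rec$rna_classes[[i]]
    if (!is.null(filter$trna_position))
      ok <- ok && strip_qual(filter$trna_position) %in% strip_qual(rec$trna_positions[[i]])
    if (!is.null(filter$mrna_region))
      ok <- ok && filter$mrna_region %in% rec$mrna_regions[[i]]
    if (!is.null(filter$motif))
      ok <- ok && filter$motif %in% rec$motifs[[i]]
    if (!is.null(filter$enzyme))
      ok <- ok && tolower(filter$enzyme) %in%
        tolower(c(rec$writers[[i]], rec$readers[[i]], rec$erasers[[i]]))
    if (!is.null(filter$status))
      ok <- ok && rec$status[i] == filter$status
    if (!is.null(filter$root_base))
      ok <- ok && rec$root_base[i] == filter$root_base
    hit[i] <- ok
  }
  sort(rec$short_name[hit])
}

# strip Newick single-quoting the way a conforming reader would
newick_unquote <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L), fixed = TRUE)
  x
}

# node depths (in edges) of an ape tree, computed from its edge matrix
ape_depths <- function(tr) {
  n_tip <- length(tr$tip.label)
  labels <- newick_unquote(c(tr$tip.label, tr$node.label))
  depth <- rep(NA_integer_, length(labels))
  root <- n_tip + 1L
  depth[root] <- 0L
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(tr$edge))) {
      a <- tr$edge[k, 1L]; b <- tr$edge[k, 2L]
      if (!is.na(depth[a]) && is.na(depth[b])) {
        depth[b] <- depth[a] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  setNames(depth, labels)
}
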