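# Indexed queries over census annotations: the content views of the
# tRNA position map and the mRNA location/motif table.

# split "22[bacteria]" into base label and kingdom qualifier
split_position <- function(x) {
  m <- regmatches(x, regexec("^([^\\[]+)(\\[([a-z]+)\\])?$", x))[[1L]]
  if (length(m) == 0L) return(c(label = x, qualifier = ""))
  c(label = m[2L], qualifier = if (length(m) >= 4L) m[4L] else "")
}

position_matches <- function(entries, filter) {
  f <- split_position(filter)
  for (e in entries) {
    s <- split_position(e)
    if (s[["label"]] == f[["label"]] &&
        (!nzchar(f[["qualifier"]]) || f[["qualifier"]] == s[["qualifier"]]))
      return(TRUE)
  }
  FALSE
}

#' Query the census
#'
#' Filters records with AND semantics across the populated arguments and
#' exact matching on stored labels (tRNA position `"34"` never matches
#' `"3"`; motif labels are compared as text, no sequence scanning).
#' Kingdom-qualified position entries such as `"22[bacteria]"` match both
#' the bare label and the qualified one.  Enzyme matching is
#' case-insensitive on gene symbols and searches writers, readers and
#' erasers unless `enzyme_role` narrows it.
#'
#' @param census a `mod_census`.
#' @param kingdom,rna_class,mrna_region,status,root_base enumeration
#'   filters (single values).
#' @param trna_position,motif,enzyme text filters.
#' @param enzyme_role optionally one of `"writers"`, `"readers"`,
#'   `"erasers"`.
#' @return The matching records, ordered by short name.
#' @examples
#' cen <- rnamod_census()
#' query_census(cen, trna_position = "58")$short_name
#' @export
query_census <- function(census, kingdom = NULL, rna_class = NULL,
                         trna_position = NULL, mrna_region = NULL,
                         motif = NULL, enzyme = NULL, enzyme_role = NULL,
                         status = NULL, root_base = NULL) {
  stopifnot(inherits(census, "mod_census"))
  check1 <- function(x, allowed, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != 1L || !x %in% allowed)
      stop("unknown ", what, " '", paste(x, collapse = ","), "'")
    x
  }
  kingdom <- check1(kingdom, KINGDOMS, "kingdom")
  rna_class <- check1(rna_class, RNA_CLASSES, "rna_class")
  mrna_region <- check1(mrna_region, MRNA_REGIONS, "mrna_region")
  status <- check1(status, PLACEMENT_STATUSES, "status")
  root_base <- check1(root_base, ROOT_BASES, "root_base")
  enzyme_role <- check1(enzyme_role, c("writers", "readers", "erasers"),
                        "enzyme_role")

  rec <- census$records
  keep <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!is.null(kingdom) && !kingdom %in% rec$kingdoms[[i]]) keep[i] <- FALSE
    else if (!is.null(rna_class) && !rna_class %in% rec$rna_classes[[i]]) keep[i] <- FALSE
    else if (!is.null(trna_position) &&
             !position_matches(rec$trna_positions[[i]], trna_position)) keep[i] <- FALSE
    else if (!is.null(mrna_region) && !mrna_region %in% rec$mrna_regions[[i]]) keep[i] <- FALSE
    else if (!is.null(motif) && !motif %in% rec$motifs[[i]]) keep[i] <- FALSE
    else if (!is.null(status) && rec$status[i] != status) keep[i] <- FALSE
    else if (!is.null(root_base) && rec$root_base[i] != root_base) keep[i] <- FALSE
    else if (!is.null(enzyme)) {
      roles <- if (is.null(enzyme_role)) c("writers", "readers", "erasers") else enzyme_role
      genes <- tolower(unlist(lapply(roles, function(rl) rec[[rl]][[i]])))
      if (!tolower(enzyme) %in% genes) keep[i] <- FALSE
    }
  }
  out <- rec[keep, , drop = FALSE]
  out <- out[order(method = "radix", out$short_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# numeric-then-suffix ordering of position labels: 20 < 20A < 20B < 21;
# non-numeric labels sort after all numeric ones
order_positions <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", labels)))
  suf <- sub("^[0-9]+", "", labels)
  labels[order(is.na(num), num, suf, method = "radix")]
}

#' Modified positions along the tRNA body
#'
#' Projects the census onto a mapping from tRNA position label to the
#' marks recorded there.  Kingdom qualifiers on position entries are
#' dropped, so `"22[bacteria]"` contributes to key `"22"`.  Keys are
#' ordered numerically with letter suffixes after their number
#' (..., 20, 20A, 20B, 21, ...); each value is a sorted character vector.
#'
#' @param census a `mod_census`.
#' @return Named list, position label -> short names.
#' @export
positions_report <- function(census) {
  stopifnot(inherits(census, "mod_census"))
  rec <- census$records
  out <- list()
  for (i in seq_len(nrow(rec))) {
    for (p in rec$trna_positions[[i]]) {
      lab <- split_position(p)[["label"]]
      out[[lab]] <- c(out[[lab]], rec$short_name[i])
    }
  }
  out <- lapply(out, function(x) sort_names(unique(x)))
  out[order_positions(names(out))]
}

#' mRNA location and motif table
#'
#' Projects the census onto a mapping from mRNA region to the marks
#' recorded there, carrying each mark's motif labels.  A record appears
#' under every region it is annotated with.
#'
#' @param census a `mod_census`.
#' @return Named list, region -> data.frame with `short_name` and
#'   `motifs` (`";"`-joined).
#' @export
mrna_map <- function(census) {
  stopifnot(inherits(census, "mod_census"))
  rec <- census$records
  out <- list()
  for (i in seq_len(nrow(rec))) {
    for (rg in rec$mrna_regions[[i]]) {
      row <- data.frame(short_name = rec$short_name[i],
                        motifs = paste(rec$motifs[[i]], collapse = LIST_SEP))
      out[[rg]] <- rbind(out[[rg]], row)
    }
  }
  out <- lapply(out, function(d) {
    d <- d[order(method = "radix", d$short_name), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  out[sort_names(names(out))]
}
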