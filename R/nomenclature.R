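# Short-name nomenclature: normalization and decomposition.
#
# A short name is tokenized into prefix tokens (each followed by a locant
# list), exactly one core token, and optional ribose suffixes.  The token
# vocabulary is data, not code: it ships as extdata/token_table.json so
# new marks extend the table without grammar changes.

.token_env <- new.env(parent = emptyenv())

token_table <- function() {
  if (is.null(.token_env$tab)) {
    path <- system.file("extdata", "token_table.json", package = "rnamodcensus",
                        mustWork = TRUE)
    tab <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    names(tab$cores) <- nfc(names(tab$cores))
    tab$aliases <- lapply(tab$aliases, nfc)
    .token_env$tab <- tab
  }
  .token_env$tab
}

#' Normalize a modification name
#'
#' NFC-normalizes the text, strips surrounding whitespace, and maps
#' registered ASCII aliases (e.g. `"psi-m"`) to their canonical Unicode
#' short names (the 2'-O-methylated pseudouridine, psi-m).  Matching
#' stays case-sensitive; unknown
#' names pass through unchanged so that the parser can report the precise
#' unconsumed token.
#'
#' @param raw a nonempty character scalar.
#' @return The canonical name.
#' @export
normalize_name <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) stop("`raw` must be a single string")
  out <- nfc(trimws(as.character(raw)))
  if (!nzchar(out)) stop("empty modification name")
  ali <- token_table()$aliases
  if (!is.null(ali[[out]])) out <- ali[[out]]
  out
}

match_core <- function(rest, tab) {
  # the remainder must be <core>, <core>m, or <core>r(p)
  hits <- list()
  for (core in names(tab$cores)) {
    if (rest == core) {
      hits[[length(hits) + 1L]] <- list(core = core, suffixes = character(0))
    } else if (rest == paste0(core, "m")) {
      hits[[length(hits) + 1L]] <- list(core = core, suffixes = "m")
    } else if (rest == paste0(core, "r(p)")) {
      hits[[length(hits) + 1L]] <- list(core = core, suffixes = "r(p)")
    }
  }
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    # prefer the exact core (e.g. "imG2" over "imG" + junk never happens,
    # but "Cm" parses as C+m, never as a core named Cm)
    exact <- Filter(function(h) length(h$suffixes) == 0L, hits)
    if (length(exact) == 1L) return(exact[[1L]])
    stop("ambiguous parse of '", rest, "'")
  }
  hits[[1L]]
}

match_prefix <- function(rest, tab) {
  # longest registered prefix token immediately followed by a locant digit
  cand <- names(tab$prefixes)
  cand <- cand[order(nchar(cand), decreasing = TRUE)]
  for (tok in cand) {
    if (startsWith(rest, tok)) {
      after <- substr(rest, nchar(tok) + 1L, nchar(tok) + 1L)
      if (grepl("^[0-9]$", after)) return(tok)
    }
  }
  NULL
}

#' Decompose a modification short name
#'
#' Parses a canonical short name into its root ribonucleoside and the
#' multiset of chemical operations separating it from that root.
#' Prefix tokens are matched left-to-right, longest first, and must carry
#' a comma-separated locant list (`"m2,2"` means methylation at N2, twice);
#' the trailing `m` and `r(p)` suffixes denote ribose 2'-O-methylation and
#' 2'-O-ribosylation.  Family symbols with idiosyncratic multi-step
#' chemistry (queuosine and wyosine families) are atomic cores: their root
#' is known but their operation count is undefined (`op_count` is `NA`).
#'
#' @param name a short name; [normalize_name()] is applied first.
#' @return A `mod_decomposition`: list with `root_base`, `operations`
#'   (data.frame `kind`, `site`, `count`), `op_count`, `canonical_name`,
#'   `atomic_core`.
#' @examples
#' parse_short_name("m2,2,7G")   # 3 methylations on guanosine
#' parse_short_name("mcm5s2U")   # 2 operations on uridine
#' @export
parse_short_name <- function(name) {
  name <- normalize_name(name)
  tab <- token_table()
  ops <- list()
  add_op <- function(kind, site) {
    key <- paste0(kind, "\r", site)
    if (is.null(ops[[key]])) ops[[key]] <<- list(kind = kind, site = site, count = 0L)
    ops[[key]]$count <<- ops[[key]]$count + 1L
  }

  rest <- name
  core <- NULL
  repeat {
    if (!nzchar(rest)) stop("no core found in '", name, "'")
    hit <- match_core(rest, tab)
    if (!is.null(hit)) { core <- hit; break }
    tok <- match_prefix(rest, tab)
    if (is.null(tok))
      stop("unknown token at '", rest, "' in '", name, "'")
    rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
    loc <- regmatches(rest, regexpr("^[0-9]+(,[0-9]+)*", rest))
    rest <- substr(rest, nchar(loc) + 1L, nchar(rest))
    kind <- tab$prefixes[[tok]]$kind
    for (site in strsplit(loc, ",", fixed = TRUE)[[1L]]) add_op(kind, site)
  }

  atomic <- isTRUE(tab$cores[[core$core]]$atomic)
  for (k in unlist(tab$cores[[core$core]]$ops)) add_op(k, "")
  for (suf in core$suffixes) {
    s <- tab$suffixes[[suf]]
    add_op(s$kind, s$site)
  }
  if (length(ops) > 0L) ops <- ops[order(names(ops), method = "radix")]
  operations <- data.frame(
    kind = vapply(ops, `[[`, "", "kind"),
    site = vapply(ops, `[[`, "", "site"),
    count = vapply(ops, `[[`, 0L, "count"),
    row.names = NULL)
  structure(list(
    root_base = tab$cores[[core$core]]$root,
    operations = operations,
    op_count = if (atomic) NA_integer_ else sum(operations$count),
    canonical_name = name,
    atomic_core = atomic), class = "mod_decomposition")
}

#' Cross-check the census against the nomenclature
#'
#' Every placed record's short name must parse, and the parsed root base
#' must agree with the curated one.  For placed records whose core is not
#' an atomic family symbol, the parsed operation count must lie between 1
#' and the curated stage: compound side-chain tokens count as one
#' operation, so the operation count is a lower bound on the stage, never
#' an upper bound.
#'
#' @param census a valid `mod_census`.
#' @return A `census_validation` report.
#' @export
check_consistency <- function(census) {
  stopifnot(inherits(census, "mod_census"))
  rec <- census$records
  placed <- rec[rec$status == "placed", , drop = FALSE]
  stage <- census_stages(census)
  v <- list()
  bad <- function(rule_id, record, message)
    v[[length(v) + 1L]] <<- data.frame(rule_id = rule_id, record = record,
                                       message = message)
  for (i in seq_len(nrow(placed))) {
    nm <- placed$short_name[i]
    dec <- tryCatch(parse_short_name(nm), error = function(e) e)
    if (inherits(dec, "error")) {
      bad("parse-failure", nm, conditionMessage(dec))
      next
    }
    if (dec$root_base != placed$root_base[i])
      bad("root-mismatch", nm,
          paste0("parsed root ", dec$root_base, " but curated root ",
                 placed$root_base[i]))
    st <- stage[[nm]]
    if (!dec$atomic_core && !is.na(st)) {
      if (dec$op_count < 1L)
        bad("zero-op-count", nm, "placed non-root record parses to 0 operations")
      else if (dec$op_count > st)
        bad("op-count-exceeds-stage", nm,
            paste0("op_count ", dec$op_count, " exceeds curated stage ", st))
    }
  }
  violations <- if (length(v) > 0L) do.call(rbind, v)
    else data.frame(rule_id = character(0), record = character(0), message = character(0))
  structure(list(violations = violations, ok = nrow(violations) == 0L),
            class = "census_validation")
}

# curated stage of every placed record, by parent-chain walk (NA on defect)
census_stages <- function(census) {
  rec <- census$records
  parent_of <- setNames(rec$parent, rec$short_name)
  status_of <- setNames(rec$status, rec$short_name)
  out <- setNames(rep(NA_integer_, nrow(rec)), rec$short_name)
  for (nm in rec$short_name) {
    if (status_of[[nm]] != "placed") next
    depth <- 1L
    cur <- nm
    ok <- TRUE
    seen <- character(0)
    while (nzchar(parent_of[[cur]])) {
      if (cur %in% seen || depth > length(parent_of)) { ok <- FALSE; break }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      if (!cur %in% names(parent_of)) { ok <- FALSE; break }
      depth <- depth + 1L
    }
    if (ok) out[[nm]] <- depth
  }
  out
}

#' @export
print.mod_decomposition <- function(x, ...) {
  cat("name:", x$canonical_name, "\n")
  cat("root:", x$root_base, "\n")
  if (x$atomic_core) {
    cat("atomic family symbol; operations not decomposed\n")
  } else if (nrow(x$operations) == 0L) {
    cat("operations: none (unmodified base)\n")
  } else {
    cat("operations (", x$op_count, " total):\n", sep = "")
    for (i in seq_len(nrow(x$operations)))
      cat(sprintf("  %s%s x%d\n", x$operations$kind[i],
                  if (nzchar(x$operations$site[i]))
                    paste0(" @", x$operations$site[i]) else "",
                  x$operations$count[i]))
  }
  invisible(x)
}
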