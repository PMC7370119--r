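# Census container, readers/writers and validators.
#
# A census is the curated collection of modification records.  Records live
# in a data.frame with one row per mark; multi-valued fields are list
# columns of character vectors (character(0) = absent), scalar fields are
# character ("" = absent).

CENSUS_COLUMNS <- c(
  "short_name", "ascii_alias", "full_name", "status", "root_base", "parent",
  "alt_parents", "kingdoms", "rna_classes", "trna_positions", "mrna_regions",
  "motifs", "writers", "readers", "erasers", "reversible",
  "stoichiometry_note", "notes", "refs")

CENSUS_LIST_COLUMNS <- c(
  "alt_parents", "kingdoms", "rna_classes", "trna_positions", "mrna_regions",
  "motifs", "writers", "readers", "erasers", "refs")

KINGDOMS <- c("eukarya", "bacteria", "archaea")
RNA_CLASSES <- c("tRNA", "rRNA", "mRNA", "lncRNA", "snRNA", "snoRNA",
                 "miRNA", "piRNA", "tsRNA", "viral")
MRNA_REGIONS <- c("5'UTR", "CDS", "near-start", "near-stop", "3'UTR",
                  "cap-adjacent", "internal-exon")
PLACEMENT_STATUSES <- c("placed", "unplaced", "nascent")
REVERSIBLE_VALUES <- c("yes", "no", "unknown")
ROOT_BASES <- c("A", "C", "G", "U")

LIST_SEP <- ";"  # list separator for ALL multi-valued columns (short names contain commas)

nfc <- function(x) stringi::stri_trans_nfc(x)

#' Construct a census from a record table
#'
#' Low-level constructor: wraps a record data.frame into a census object
#' after structural checks (column names and types) and Unicode (NFC)
#' normalization.  No semantic validation is performed, so deliberately
#' broken censuses can be built for inspection with [validate_census()];
#' [load_census()] applies the hard input checks.
#'
#' @param records data.frame with the census columns; multi-valued columns
#'   may be given either as list columns of character vectors or as
#'   `";"`-separated strings.
#' @param version,source_note census metadata strings.
#' @return An object of class `mod_census` with elements `records`,
#'   `version` and `source_note`.
#' @export
as_census <- function(records, version = "", source_note = "") {
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  missing_cols <- setdiff(CENSUS_COLUMNS, names(records))
  if (length(missing_cols) > 0L)
    stop("missing census columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(records), CENSUS_COLUMNS)
  if (length(extra) > 0L)
    stop("unknown census columns: ", paste(extra, collapse = ", "))
  records <- records[, CENSUS_COLUMNS, drop = FALSE]
  for (col in CENSUS_COLUMNS) {
    v <- records[[col]]
    if (col %in% CENSUS_LIST_COLUMNS) {
      if (!is.list(v)) {
        v <- lapply(as.character(v), function(s) {
          if (is.na(s) || !nzchar(s)) character(0)
          else nfc(strsplit(s, LIST_SEP, fixed = TRUE)[[1L]])
        })
      } else {
        v <- lapply(v, function(s) if (length(s) == 0L) character(0) else nfc(as.character(s)))
      }
      records[[col]] <- I(v)
    } else {
      s <- as.character(v)
      s[is.na(s)] <- ""
      records[[col]] <- nfc(s)
    }
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 version = nfc(as.character(version)),
                 source_note = nfc(as.character(source_note))),
            class = "mod_census")
}

#' Load a census from TSV or JSON
#'
#' Reads the census dialects: a UTF-8 tab-separated table with a fixed
#' header (optionally preceded by `# key: value` metadata comment lines),
#' or a JSON object `{version, source_note, records: [...]}` whose record
#' keys match the TSV columns.  Multi-valued cells use `";"` as the list
#' separator because canonical short names themselves contain commas
#' (`m2,2G`).  All text is Unicode-normalized (NFC).
#'
#' Hard errors (rather than validation-report entries) are raised for
#' structural defects of the input: unknown or missing columns, duplicate
#' short names, parents that do not resolve, and malformed enumeration
#' values (with the offending row and column named).
#'
#' @param source path to a file, or a character string holding the raw
#'   document itself.
#' @param format `"tsv"`, `"json"`, or `"auto"` (sniffed from the file
#'   extension or content).
#' @return A `mod_census` object.
#' @seealso [write_census()], [validate_census()], [rnamod_census()]
#' @examples
#' cen <- rnamod_census()
#' nrow(cen$records)
#' @export
load_census <- function(source, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  if (is_path) {
    text <- readChar(source, file.info(source)$size, useBytes = TRUE)
    Encoding(text) <- "UTF-8"
    if (format == "auto")
      format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "tsv"
  } else {
    text <- paste(as.character(source), collapse = "\n")
    if (format == "auto")
      format <- if (grepl("^\\s*\\{", text)) "json" else "tsv"
  }
  cen <- if (format == "tsv") parse_census_tsv(text) else parse_census_json(text)
  check_census_input(cen)
  cen
}

parse_census_tsv <- function(text) {
  lines <- strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1L]]
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  meta <- character(0)
  while (length(lines) > 0L && startsWith(lines[1L], "#")) {
    meta <- c(meta, lines[1L]); lines <- lines[-1L]
  }
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return("")
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
  }
  if (length(lines) == 0L) stop("TSV census has no header row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, CENSUS_COLUMNS)) {
    extra <- setdiff(header, CENSUS_COLUMNS)
    missing <- setdiff(CENSUS_COLUMNS, header)
    msg <- "TSV header does not match the census dialect"
    if (length(extra)) msg <- paste0(msg, "; unknown columns: ", paste(extra, collapse = ", "))
    if (length(missing)) msg <- paste0(msg, "; missing columns: ", paste(missing, collapse = ", "))
    stop(msg)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  cells <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  nc <- length(CENSUS_COLUMNS)
  cells <- lapply(seq_along(cells), function(i) {
    x <- cells[[i]]
    if (length(x) > nc)
      stop("row ", i, ": ", length(x), " fields, expected ", nc)
    c(x, rep("", nc - length(x)))
  })
  mat <- do.call(rbind, cells)
  records <- as.data.frame(mat, stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L)
    records <- as.data.frame(setNames(rep(list(character(0)), nc), CENSUS_COLUMNS))
  names(records) <- CENSUS_COLUMNS
  as_census(records, version = get_meta("version"), source_note = get_meta("source_note"))
}

parse_census_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(obj) || is.null(obj$records))
    stop("JSON census must be an object with a 'records' array")
  known <- c("version", "source_note", "records", "comment")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0L)
    stop("unknown top-level JSON keys: ", paste(extra, collapse = ", "))
  recs <- obj$records
  rows <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    extra <- setdiff(names(rec), CENSUS_COLUMNS)
    if (length(extra) > 0L)
      stop("record ", i, ": unknown columns: ", paste(extra, collapse = ", "))
    out <- setNames(vector("list", length(CENSUS_COLUMNS)), CENSUS_COLUMNS)
    for (col in CENSUS_COLUMNS) {
      v <- rec[[col]]
      if (col %in% CENSUS_LIST_COLUMNS) {
        out[[col]] <- if (is.null(v)) character(0) else unlist(v, use.names = FALSE)
      } else {
        out[[col]] <- if (is.null(v)) "" else as.character(v)[1L]
      }
    }
    out
  })
  records <- data.frame(short_name = vapply(rows, `[[`, "", "short_name"),
                        stringsAsFactors = FALSE)
  for (col in CENSUS_COLUMNS) {
    records[[col]] <- if (col %in% CENSUS_LIST_COLUMNS)
      I(lapply(rows, `[[`, col)) else vapply(rows, `[[`, "", col)
  }
  as_census(records,
            version = if (is.null(obj$version)) "" else obj$version,
            source_note = if (is.null(obj$source_note)) "" else obj$source_note)
}

# Hard input checks applied at load time.
check_census_input <- function(cen) {
  rec <- cen$records
  dup <- rec$short_name[duplicated(rec$short_name)]
  if (length(dup) > 0L) {
    d <- dup[1L]
    stop("duplicate short_name '", d, "' (rows ",
         paste(which(rec$short_name == d), collapse = " and "), ")")
  }
  known <- rec$short_name
  for (i in seq_len(nrow(rec))) {
    p <- rec$parent[i]
    if (nzchar(p) && !(p %in% known))
      stop("row ", i, " ('", rec$short_name[i], "'): unresolvable parent '", p, "'")
    bad_alt <- setdiff(rec$alt_parents[[i]], known)
    if (length(bad_alt) > 0L)
      stop("row ", i, " ('", rec$short_name[i], "'): unresolvable alt_parent '",
           bad_alt[1L], "'")
  }
  enum_check <- function(col, allowed, values_of_row) {
    for (i in seq_len(nrow(rec))) {
      bad <- setdiff(values_of_row(i), c(allowed, ""))
      if (length(bad) > 0L)
        stop("row ", i, " ('", rec$short_name[i], "'), column '", col,
             "': malformed value '", bad[1L], "'")
    }
  }
  enum_check("status", PLACEMENT_STATUSES, function(i) rec$status[i])
  enum_check("root_base", ROOT_BASES, function(i) rec$root_base[i])
  enum_check("reversible", REVERSIBLE_VALUES, function(i) rec$reversible[i])
  enum_check("kingdoms", KINGDOMS, function(i) rec$kingdoms[[i]])
  enum_check("rna_classes", RNA_CLASSES, function(i) rec$rna_classes[[i]])
  enum_check("mrna_regions", MRNA_REGIONS, function(i) rec$mrna_regions[[i]])
  invisible(cen)
}

#' Serialize a census to TSV or JSON
#'
#' Output is byte-stable: records are written in input order, list fields
#' are `";"`-joined, and the JSON dialect uses a deterministic key order.
#' An invalid census (see [validate_census()]) is refused; the error
#' carries the validation report in its `report` field.
#'
#' @param census a `mod_census`.
#' @param format `"tsv"` or `"json"`.
#' @param path optional output file; when `NULL` the document is returned
#'   as a single character string.
#' @return The document text, invisibly when written to `path`.
#' @export
write_census <- function(census, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(census, "mod_census"))
  report <- validate_census(census)
  if (!report$ok) {
    cond <- structure(
      class = c("census_invalid", "error", "condition"),
      list(message = paste0("refusing to write an invalid census (",
                            nrow(report$violations), " violation(s)); ",
                            "see the 'report' field of this condition"),
           call = sys.call(), report = report))
    stop(cond)
  }
  rec <- census$records
  text <- if (format == "tsv") {
    join <- function(col) vapply(rec[[col]], paste, "", collapse = LIST_SEP)
    cells <- lapply(CENSUS_COLUMNS, function(col)
      if (col %in% CENSUS_LIST_COLUMNS) join(col) else rec[[col]])
    body <- do.call(paste, c(cells, sep = "\t"))
    paste(c(paste0("# version: ", census$version),
            paste0("# source_note: ", census$source_note),
            paste(CENSUS_COLUMNS, collapse = "\t"),
            body, ""), collapse = "\n")
  } else {
    recs <- lapply(seq_len(nrow(rec)), function(i) {
      out <- setNames(vector("list", length(CENSUS_COLUMNS)), CENSUS_COLUMNS)
      for (col in CENSUS_COLUMNS) {
        out[[col]] <- if (col %in% CENSUS_LIST_COLUMNS)
          as.list(rec[[col]][[i]]) else rec[[col]][i]
      }
      out
    })
    jsonlite::toJSON(list(version = census$version,
                          source_note = census$source_note,
                          records = recs),
                     auto_unbox = TRUE, pretty = TRUE)
  }
  text <- as.character(text)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}

#' Validate a census
#'
#' Checks every record-level and collection-level invariant of the census
#' model: unique non-empty short names, legal enumeration values, placed
#' records carrying a root base, parents resolving to placed records with
#' the same root base, terminating (acyclic) parent chains, nascent
#' records carrying neither parent nor root base, and annotation fields
#' implying the matching RNA class.  Violations are data, not exceptions.
#'
#' @param census a `mod_census`.
#' @return A `census_validation` object: list with `violations`
#'   (data.frame `rule_id`, `record`, `message`) and `ok`.
#' @export
validate_census <- function(census) {
  stopifnot(inherits(census, "mod_census"))
  rec <- census$records
  v <- list()
  bad <- function(rule_id, record, message)
    v[[length(v) + 1L]] <<- data.frame(rule_id = rule_id, record = record,
                                       message = message)

  dup <- unique(rec$short_name[duplicated(rec$short_name)])
  for (d in dup)
    bad("duplicate-short-name", d,
        paste0("short_name '", d, "' appears ", sum(rec$short_name == d), " times"))
  idx <- match(rec$short_name, rec$short_name)  # first occurrence wins for lookups

  for (i in seq_len(nrow(rec))) {
    nm <- rec$short_name[i]
    status <- rec$status[i]
    root <- rec$root_base[i]
    parent <- rec$parent[i]

    if (!nzchar(nm)) bad("empty-short-name", "", paste0("row ", i, " has an empty short_name"))
    if (!status %in% PLACEMENT_STATUSES)
      bad("bad-status", nm, paste0("status '", status, "' is not one of ",
                                   paste(PLACEMENT_STATUSES, collapse = "/")))
    if (nzchar(root) && !root %in% ROOT_BASES)
      bad("bad-root-base", nm, paste0("root_base '", root, "'"))
    if (!rec$reversible[i] %in% REVERSIBLE_VALUES)
      bad("bad-enum", nm, paste0("reversible '", rec$reversible[i], "'"))
    for (spec in list(c("kingdoms"), c("rna_classes"), c("mrna_regions"))) {
      col <- spec[1L]
      allowed <- switch(col, kingdoms = KINGDOMS, rna_classes = RNA_CLASSES,
                        mrna_regions = MRNA_REGIONS)
      unk <- setdiff(rec[[col]][[i]], allowed)
      if (length(unk) > 0L)
        bad("bad-enum", nm, paste0(col, " value '", unk[1L], "'"))
    }

    if (status == "placed" && !nzchar(root))
      bad("placed-missing-root", nm, "placed record without root_base")
    if (status == "nascent") {
      if (nzchar(parent)) bad("nascent-has-parent", nm,
                              paste0("nascent record has parent '", parent, "'"))
      if (nzchar(root)) bad("nascent-has-root", nm,
                            paste0("nascent record has root_base '", root, "'"))
    }
    if (status == "unplaced" && nzchar(parent))
      bad("unplaced-has-parent", nm, paste0("unplaced record has parent '", parent, "'"))

    refs <- c(parent[nzchar(parent)], rec$alt_parents[[i]])
    for (p in refs) {
      j <- idx[match(p, rec$short_name)]
      if (is.na(j)) {
        bad("unresolvable-parent", nm, paste0("reference '", p, "' does not resolve"))
      } else if (p == parent && status == "placed") {
        if (rec$status[j] != "placed")
          bad("parent-not-placed", nm, paste0("parent '", p, "' has status '",
                                              rec$status[j], "'"))
        else if (nzchar(root) && rec$root_base[j] != root)
          bad("parent-root-mismatch", nm,
              paste0("parent '", p, "' is rooted at ", rec$root_base[j],
                     " but record is rooted at ", root))
      }
    }

    if (length(rec$trna_positions[[i]]) > 0L && !"tRNA" %in% rec$rna_classes[[i]])
      bad("trna-position-without-trna-class", nm,
          "trna_positions set but tRNA not among rna_classes")
    if ((length(rec$mrna_regions[[i]]) > 0L || length(rec$motifs[[i]]) > 0L) &&
        !"mRNA" %in% rec$rna_classes[[i]])
      bad("mrna-annotation-without-mrna-class", nm,
          "mrna_regions/motifs set but mRNA not among rna_classes")
  }

  # parent chains must terminate
  parent_of <- setNames(rec$parent, rec$short_name)
  flagged <- character(0)
  for (nm in rec$short_name) {
    seen <- character(0)
    cur <- nm
    repeat {
      if (cur %in% seen) {
        cyc <- seen[which(seen == cur):length(seen)]
        key <- paste(sort(cyc), collapse = "|")
        if (!key %in% flagged) {
          flagged <- c(flagged, key)
          bad("parent-cycle", cur,
              paste0("parent chain cycles through: ", paste(cyc, collapse = " -> ")))
        }
        break
      }
      seen <- c(seen, cur)
      nxt <- parent_of[[cur]]
      if (is.null(nxt) || is.na(nxt) || !nzchar(nxt) || !nxt %in% names(parent_of)) break
      cur <- nxt
    }
  }

  violations <- if (length(v) > 0L) do.call(rbind, v)
    else data.frame(rule_id = character(0), record = character(0), message = character(0))
  structure(list(violations = violations, ok = nrow(violations) == 0L),
            class = "census_validation")
}

#' The packaged census
#'
#' Loads the curated census shipped with the package: 134 placed records
#' forming the four modification trees, 3 unplaced marks, and 21
#' nascent-transcript end marks (placeholder names; only their count is
#' curated from the printed total).
#'
#' @return A `mod_census`.
#' @export
rnamod_census <- function() {
  path <- system.file("extdata", "census.tsv", package = "rnamodcensus",
                      mustWork = TRUE)
  load_census(path, format = "tsv")
}

#' Look up one record by short name or ASCII alias
#'
#' Accepts the canonical Unicode short name, the ASCII alias, or any text
#' that [normalize_name()] maps to a canonical name.
#'
#' @param census a `mod_census`.
#' @param name modification name.
#' @return A one-row data.frame, or an error for unknown names.
#' @export
census_record <- function(census, name) {
  stopifnot(inherits(census, "mod_census"))
  rec <- census$records
  name <- nfc(trimws(name))
  i <- match(name, rec$short_name)
  if (is.na(i)) i <- match(name, rec$ascii_alias)
  if (is.na(i)) i <- match(normalize_name(name), rec$short_name)
  if (is.na(i)) stop("unknown modification name '", name, "'")
  rec[i, , drop = FALSE]
}

#' @export
print.mod_census <- function(x, ...) {
  st <- table(factor(x$records$status, levels = PLACEMENT_STATUSES))
  cat("RNA modification census", if (nzchar(x$version)) paste0("v", x$version), "\n")
  cat("  records:", nrow(x$records),
      sprintf("(%d placed, %d unplaced, %d nascent)\n",
              st[["placed"]], st[["unplaced"]], st[["nascent"]]))
  if (nzchar(x$source_note)) cat(" ", x$source_note, "\n")
  invisible(x)
}

#' @export
summary.mod_census <- function(object, ...) {
  placed <- object$records[object$records$status == "placed", ]
  cat("Placed records by root base:\n")
  print(table(factor(placed$root_base, levels = ROOT_BASES)))
  invisible(object)
}

#' @export
print.census_validation <- function(x, ...) {
  if (x$ok) {
    cat("census OK: no violations\n")
  } else {
    cat("census INVALID:", nrow(x$violations), "violation(s)\n")
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s: %s\n", x$violations$rule_id[i],
                  x$violations$record[i], x$violations$message[i]))
  }
  invisible(x)
}
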