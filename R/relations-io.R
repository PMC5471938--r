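#' Read a predication file
#'
#' Parses one of two tabular dialects into a [PredicationSet-class]:
#'
#' * `simple-tsv` — tab-separated with header
#'   `pmid  date  subject_cui  predicate  object_cui  negated`
#'   (`negated` in 0/1, dates ISO-8601 days or bare years).
#' * `semmeddb-csv` — a comma-separated export of a SemMedDB-style
#'   PREDICATION table with (at least) columns `PMID`, `PREDICATE`,
#'   `SUBJECT_CUI`, `OBJECT_CUI` (case-insensitive header). Negation is
#'   carried by the `NEG_` predicate prefix, which is stripped into the
#'   negation flag. Publication dates come from a separate two-column
#'   TSV (`pmid`, `date`) passed as `datesPath`.
#'
#' Malformed rows (unparseable date, empty/ill-formed CUIs, empty predicate,
#' bad negation value) are counted, reported via a message, and dropped;
#' negated rows are retained and merely flagged — exclusion happens when the
#' adjacency matrix is built.
#'
#' @param path input file path.
#' @param dialect `"simple-tsv"` or `"semmeddb-csv"`.
#' @param datesPath for `semmeddb-csv`: TSV mapping PMID to date.
#' @return a [PredicationSet-class]; its filter log records the parse.
#' @export
readPredications <- function(path, dialect = "simple-tsv", datesPath = NULL) {
  if (!dialect %in% c("simple-tsv", "semmeddb-csv"))
    stopConfig("unknown predication dialect: '%s'", dialect)
  if (!file.exists(path)) stopInput("predication file not found: %s", path)

  if (dialect == "simple-tsv") {
    raw <- utils::read.delim(path, colClasses = "character",
                             stringsAsFactors = FALSE)
    need <- predicationColumns
    if (!all(need %in% names(raw)))
      stopInput("simple-tsv header must contain: %s",
                paste(need, collapse = ", "))
    raw <- raw[need]
    raw$negflag <- raw$negated %in% c("1", "true", "TRUE")
    badNeg <- !(raw$negated %in% c("0", "1", "true", "false", "TRUE", "FALSE"))
  } else {
    raw0 <- utils::read.csv(path, colClasses = "character",
                            stringsAsFactors = FALSE)
    names(raw0) <- toupper(names(raw0))
    need <- c("PMID", "PREDICATE", "SUBJECT_CUI", "OBJECT_CUI")
    if (!all(need %in% names(raw0)))
      stopInput("semmeddb-csv header must contain: %s",
                paste(need, collapse = ", "))
    if (is.null(datesPath))
      stopConfig("semmeddb-csv requires a PMID->date table (datesPath)")
    dates <- utils::read.delim(datesPath, colClasses = "character",
                               stringsAsFactors = FALSE)
    if (!all(c("pmid", "date") %in% names(dates)))
      stopInput("dates table must have columns pmid, date")
    negflag <- startsWith(raw0$PREDICATE, "NEG_")
    raw <- data.frame(
      pmid = raw0$PMID,
      date = dates$date[match(raw0$PMID, dates$pmid)],
      subject_cui = raw0$SUBJECT_CUI,
      predicate = sub("^NEG_", "", raw0$PREDICATE),
      object_cui = raw0$OBJECT_CUI,
      negated = ifelse(negflag, "1", "0"),
      stringsAsFactors = FALSE)
    raw$date[is.na(raw$date)] <- ""
    raw$negflag <- negflag
    badNeg <- rep(FALSE, nrow(raw))
  }

  dts <- normalizeDate(raw$date)
  bad <- is.na(dts) | badNeg |
    !isValidCui(raw$subject_cui) | !isValidCui(raw$object_cui) |
    raw$predicate == ""
  nMalformed <- sum(bad)
  if (nMalformed > 0)
    message(sprintf("readPredications: dropped %d malformed row(s) from %s",
                    nMalformed, path))
  keep <- which(!bad)
  if (length(keep) == 0)
    stopInput("no parseable predication rows in %s", path)

  df <- data.frame(
    pmid = raw$pmid[keep], date = dts[keep],
    subject_cui = raw$subject_cui[keep], predicate = raw$predicate[keep],
    object_cui = raw$object_cui[keep], negated = raw$negflag[keep],
    stringsAsFactors = FALSE)
  ps <- PredicationSet(df, provenance = path)
  logFilterStep(ps, "read",
                sprintf("dialect=%s malformed=%d", dialect, nMalformed),
                nrow(raw), nrow(df))
}

#' Write a PredicationSet as simple-tsv
#'
#' The written file round-trips through [readPredications()] field-for-field.
#'
#' @param preds a [PredicationSet-class].
#' @param path output path.
#' @return (invisibly) the number of rows written.
#' @export
writePredications <- function(preds, path) {
  stopifnot(is(preds, "PredicationSet"))
  df <- predications(preds)
  out <- data.frame(
    pmid = df$pmid, date = format(df$date, "%Y-%m-%d"),
    subject_cui = df$subject_cui, predicate = df$predicate,
    object_cui = df$object_cui, negated = as.integer(df$negated),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(nrow(out))
}

#' Read a concept table
#'
#' Tab-separated with header `cui  name  semantic_types`, the last column a
#' pipe-separated list of semantic-type codes. Duplicate CUI rows merge
#' their semantic-type sets (the first-seen name wins).
#'
#' @param path input file path.
#' @return a [ConceptTable-class].
#' @export
readConcepts <- function(path) {
  if (!file.exists(path)) stopInput("concept file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty concept table: ", path)
    return(ConceptTable())
  }
  if (!all(c("cui", "name", "semantic_types") %in% names(raw)))
    stopInput("concept table header must be: cui, name, semantic_types")
  if (any(trimws(raw$semantic_types) == ""))
    stopInput("concept table has CUI(s) with empty semantic-type field")
  sts <- strsplit(raw$semantic_types, "|", fixed = TRUE)
  first <- !duplicated(raw$cui)
  cui <- raw$cui[first]
  name <- raw$name[first]
  merged <- lapply(cui, function(id) {
    sort(unique(unlist(sts[raw$cui == id])))
  })
  ConceptTable(cui = cui, name = name, semTypes = merged)
}

#' Read source-asserted synonym assertions
#'
#' Tab-separated with header `cui_a  cui_b  source`. Pairs are unordered:
#' (a, b) and (b, a) from the same source collapse to one assertion.
#' Self-pairs are dropped with a warning.
#'
#' @param path input file path.
#' @return data.frame with columns `cui_a`, `cui_b` (ordered so
#'   `cui_a < cui_b`) and `source`, deduplicated per (pair, source).
#' @export
readSynonymAssertions <- function(path) {
  if (!file.exists(path)) stopInput("synonym file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  empty <- data.frame(cui_a = character(), cui_b = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(empty)
  if (!all(c("cui_a", "cui_b", "source") %in% names(raw)))
    stopInput("synonym file header must be: cui_a, cui_b, source")
  self <- raw$cui_a == raw$cui_b
  if (any(self)) {
    warning(sprintf("dropped %d self-pair synonym assertion(s)", sum(self)))
    raw <- raw[!self, , drop = FALSE]
  }
  if (nrow(raw) == 0) return(empty)
  p <- orderPair(raw$cui_a, raw$cui_b)
  out <- data.frame(cui_a = p$a, cui_b = p$b, source = raw$source,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("cui_a", "cui_b", "source")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hidden pairs (with optional linking-chain evidence)
#'
#' One row per hidden pair: `cui_a  cui_b  depth  chains`, sorted by
#' (cui_a, cui_b, depth). Chains are formatted `A>b1>b2>C` and multiple
#' chains for one pair are pipe-joined.
#'
#' @param path output path (parent directory must exist).
#' @param pairs a [HiddenPairSet-class].
#' @param chains optional named list of character vectors of chain strings;
#'   names are `"<cui_a>:<cui_b>"` with `cui_a < cui_b`.
#' @return the number of data rows written.
#' @export
writeHiddenPairs <- function(path, pairs, chains = NULL) {
  stopifnot(is(pairs, "HiddenPairSet"))
  if (!dir.exists(dirname(path)))
    stopInput("output directory does not exist: %s", dirname(path))
  df <- hiddenPairTable(pairs)
  df <- df[order(df$cui_a, df$cui_b, df$depth), , drop = FALSE]
  chainCol <- rep("", nrow(df))
  if (!is.null(chains) && nrow(df) > 0) {
    key <- paste(df$cui_a, df$cui_b, sep = ":")
    hit <- match(key, names(chains))
    chainCol <- ifelse(is.na(hit), "",
                       vapply(hit, function(i) {
                         if (is.na(i)) "" else paste(chains[[i]], collapse = "|")
                       }, ""))
  }
  out <- data.frame(cui_a = df$cui_a, cui_b = df$cui_b, depth = df$depth,
                    chains = chainCol, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  nrow(out)
}

#' Format a linking chain as its compact string form
#'
#' @param chain a chain as returned by [linkingChains()].
#' @return a string `A>b1>...>C`.
#' @export
formatChain <- function(chain) {
  paste(c(chain$source, chain$links, chain$target), collapse = ">")
}
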