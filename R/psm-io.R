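#' @details
#' On-disk PSM tables are tab-separated with a header row and columns
#' exactly `psm_id, experiment_id, peptide, accession, score, is_decoy,
#' i114, i115, i116, i117`; `is_decoy` is 0/1 and an empty intensity field
#' means missing.  All readers in the package reject malformed rows with
#' the offending row number rather than silently coercing them.
#' @name itraqpipe-io
NULL

.psm_columns <- c("psm_id", "experiment_id", "peptide", "accession",
                  "score", "is_decoy", "i114", "i115", "i116", "i117")
.intensity_columns <- c("i114", "i115", "i116", "i117")

#' Write a PSM table
#'
#' @param psms PSM data frame as produced by [generate_experiment()] or
#'   [read_psm_table()]; must be non-empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_psm_table()] for the round-trip reader.
#' @export
write_psm_table <- function(psms, path) {
  if (is.null(psms) || nrow(psms) == 0L)
    stop("refusing to write an empty PSM table", call. = FALSE)
  missing_cols <- setdiff(.psm_columns, names(psms))
  if (length(missing_cols))
    stop("PSM table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- psms[, .psm_columns]
  out$is_decoy <- as.integer(out$is_decoy)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a PSM table
#'
#' Validates the header and every row: scores must be numeric and finite,
#' `is_decoy` must be 0/1, intensities must be non-negative numbers or
#' empty (missing).  Violations raise an error naming the offending data
#' row.
#'
#' @param path Path to a tab-separated PSM table.
#' @return A PSM data frame (see [itraqpipe-io] for the column contract)
#'   with logical `is_decoy` and `NA` for missing intensities.
#' @export
read_psm_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!identical(names(raw), .psm_columns))
    stop("malformed PSM table header in '", path, "': expected columns ",
         paste(.psm_columns, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  fail <- function(row, what)
    stop("parse error in '", path, "' at data row ", row, ": ", what,
         call. = FALSE)
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(!is.finite(score))
  if (length(bad)) fail(bad[1], paste0("non-numeric score '", raw$score[bad[1]], "'"))
  if (any(bad <- !raw$is_decoy %in% c("0", "1")))
    fail(which(bad)[1], paste0("is_decoy must be 0/1, got '",
                               raw$is_decoy[which(bad)[1]], "'"))
  ints <- lapply(.intensity_columns, function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    v[x == ""] <- NA_real_
    bad <- which(x != "" & (is.na(v) | v < 0))
    if (length(bad))
      fail(bad[1], paste0("invalid intensity '", x[bad[1]], "' in ", col))
    v
  })
  names(ints) <- .intensity_columns
  df <- data.frame(psm_id = raw$psm_id,
                   experiment_id = raw$experiment_id,
                   peptide = raw$peptide,
                   accession = raw$accession,
                   score = score,
                   is_decoy = raw$is_decoy == "1",
                   stringsAsFactors = FALSE)
  for (col in .intensity_columns) df[[col]] <- ints[[col]]
  df
}

# md5 checksums pinning the packaged reference-table transcriptions
.fixture_files <- c(T1A = "table1a.tsv", T1B = "table1b.tsv",
                    T2 = "table2.tsv", T3 = "table3.tsv")
.fixture_md5 <- c(T1A = "2f94fce3495205dc30cdba1ea3bf3d5b",
                  T1B = "9a99118b9c315e82832dacf495c44106",
                  T2 = "019d0010786888c0636ae68c29ba66a1",
                  T3 = "cf7eee6131ff47c869dea548c83842db")

#' Load a packaged reference protein table
#'
#' The package ships verbatim transcriptions of the source study's printed
#' protein tables: `T1A`/`T1B` are the ten most up-/downregulated proteins
#' after subarachnoid hemorrhage (vehicle vs sham), `T2` is the "group 1"
#' table (hemorrhage-induced upregulation abolished by MEK1/2 inhibition)
#' and `T3` the "group 2" table (downregulation abolished).  Values are the
#' published log2 iTRAQ ratios; unicode minus signs were normalized to
#' ASCII on transcription and each file's checksum is pinned, so a tampered
#' fixture fails loudly.
#'
#' The transcriptions preserve the printed tables exactly, including their
#' internal inconsistencies: `T2` lists four accessions twice with
#' different values, and two accessions appear in both `T2` and `T3` (see
#' [reproduce_paper_groups()]).
#'
#' @param table_id One of `"T1A"`, `"T1B"`, `"T2"`, `"T3"`.
#' @return Data frame with columns `accession`, `protein_name`,
#'   `log2_ratio`.
#' @export
load_fixture <- function(table_id) {
  if (length(table_id) != 1L || !table_id %in% names(.fixture_files))
    stop("unknown table_id '", paste(table_id, collapse = ","),
         "'; expected one of ", paste(names(.fixture_files), collapse = ", "),
         call. = FALSE)
  path <- system.file("extdata", .fixture_files[[table_id]],
                      package = "itraqpipe", mustWork = TRUE)
  .load_fixture_file(path, table_id)
}

# checksum-verified fixture parse; split out so integrity failure is testable
.load_fixture_file <- function(path, table_id) {
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[table_id]])))
    stop("fixture integrity failure for ", table_id, ": checksum ", md5,
         " does not match the pinned transcription", call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  data.frame(accession = df$accession, protein_name = df$name,
             log2_ratio = as.numeric(df$log2), stringsAsFactors = FALSE)
}

#' Extreme entries of a packaged reference table
#'
#' @param table_id As in [load_fixture()].
#' @return List with elements `max` and `min`, each a one-row data frame
#'   (ties broken by first printed occurrence).
#' @export
fixture_extremes <- function(table_id) {
  df <- load_fixture(table_id)
  list(max = df[which.max(df$log2_ratio), , drop = FALSE],
       min = df[which.min(df$log2_ratio), , drop = FALSE])
}

#' Read / write a molecular-function annotation table
#'
#' Tab-separated, two columns: accession and a semicolon-joined, non-empty
#' set of category labels drawn from the controlled vocabulary in
#' [annotation_vocabulary()].
#'
#' @param path File path.
#' @return A long-format data frame with columns `accession`, `category`
#'   (one row per accession-category pair).
#' @export
read_annotation <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", header = TRUE,
                           na.strings = NULL)
  if (!identical(names(raw), c("accession", "categories")))
    stop("malformed annotation header in '", path,
         "': expected columns accession, categories", call. = FALSE)
  vocab <- annotation_vocabulary()
  out <- lapply(seq_len(nrow(raw)), function(i) {
    cats <- strsplit(raw$categories[i], ";", fixed = TRUE)[[1]]
    cats <- trimws(cats)
    cats <- cats[nzchar(cats)]
    if (length(cats) == 0L)
      stop("parse error in '", path, "' at data row ", i,
           ": empty category set for ", raw$accession[i], call. = FALSE)
    bad <- setdiff(cats, vocab)
    if (length(bad))
      stop("parse error in '", path, "' at data row ", i,
           ": unknown category '", bad[1], "'", call. = FALSE)
    data.frame(accession = raw$accession[i], category = unique(cats),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @rdname read_annotation
#' @param annotation Long-format annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  cats <- tapply(annotation$category, annotation$accession,
                 function(x) paste(x, collapse = ";"))
  acc <- unique(annotation$accession)
  utils::write.table(
    data.frame(accession = acc, categories = unname(cats[acc])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Controlled vocabulary of molecular-function categories
#'
#' The eight categories used to summarize regulated proteins by molecular
#' function.
#'
#' @return Character vector of category labels.
#' @export
annotation_vocabulary <- function() {
  c("catalytic activity", "binding", "structural activity",
    "enzyme regulator activity", "transcription factor activity",
    "receptor activity", "translation", "transporter")
}

#' Read / write a protein-interaction edge list
#'
#' Tab-separated with columns `accession_a`, `accession_b`, `score`
#' (confidence in \[0, 1\]).  Edges are undirected; duplicates in either
#' orientation are collapsed keeping the maximum score.  Self-edges are
#' rejected.  An empty file yields an empty edge set.
#'
#' @param path File path.
#' @return Data frame with columns `accession_a`, `accession_b`, `score`,
#'   one row per undirected edge, endpoints in lexicographic order.
#' @export
read_edges <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", header = TRUE,
                           na.strings = NULL)
  if (!identical(names(raw), c("accession_a", "accession_b", "score")))
    stop("malformed edge-list header in '", path,
         "': expected columns accession_a, accession_b, score", call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(accession_a = character(), accession_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(!is.finite(score) | score < 0 | score > 1)
  if (length(bad))
    stop("parse error in '", path, "' at data row ", bad[1],
         ": score must be a number in [0,1], got '", raw$score[bad[1]], "'",
         call. = FALSE)
  self <- which(raw$accession_a == raw$accession_b)
  if (length(self))
    stop("parse error in '", path, "' at data row ", self[1],
         ": self-edge on ", raw$accession_a[self[1]], call. = FALSE)
  a <- pmin(raw$accession_a, raw$accession_b)
  b <- pmax(raw$accession_a, raw$accession_b)
  key <- paste(a, b, sep = "\r")
  best <- tapply(score, key, max)
  keys <- unique(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(accession_a = vapply(parts, `[`, "", 1L),
             accession_b = vapply(parts, `[`, "", 2L),
             score = unname(best[keys]),
             stringsAsFactors = FALSE)
}

#' @rdname read_edges
#' @param edges Edge data frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[, c("accession_a", "accession_b", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
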