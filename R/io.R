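# FASTA input and the tab-separated CNE table (BED-style 0-based half-open
# coordinates, identity with exactly four decimals).

#' Read a (multi-record) FASTA file
#'
#' Record names are the first whitespace-delimited token of each header and
#' must be unique. Case is preserved so that soft-masking (lowercase) can be
#' consumed by [build_mask()]. IUPAC ambiguity codes are converted to `N`
#' (case kept) with a message stating the count; any character outside the
#' IUPAC DNA alphabet is an error naming its position.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("no sequences found in FASTA: ", path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s) in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- stats::setNames(as.character(set), nm)

  bad <- regexpr("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", seqs, perl = TRUE)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-IUPAC character '", substr(seqs[i], bad[i], bad[i]),
         "' in sequence '", nm[i], "' at position ", bad[i])
  }
  n_amb <- sum(nchar(seqs) -
                 nchar(gsub("[URYSWKMBDHVuryswkmbdhv]", "", seqs, perl = TRUE)))
  if (n_amb > 0L) {
    message("read_fasta: converted ", n_amb, " ambiguity base(s) to N")
    seqs[] <- chartr("URYSWKMBDHVuryswkmbdhv",
                     paste0(strrep("N", 11L), strrep("n", 11L)), seqs)
  }
  seqs
}

#' Write hits as a tab-separated CNE table
#'
#' One row per hit with columns `ref_name`, `ref_start`, `ref_end`,
#' `query_name`, `query_start`, `query_end`, `ref_len`, `query_len`,
#' `edit_distance`, `identity` (exactly four decimals), `query_strand`.
#' Coordinates are 0-based half-open (BED convention). `#`-prefixed header
#' lines record the tool version and the full parameter set.
#'
#' @param hits Hit data.frame (deduplicated and sorted, as returned by
#'   [discover_cnes()]).
#' @param path Output file.
#' @param params Optional [cne_params()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_cnes <- function(hits, path, params = NULL) {
  if (is.null(params)) params <- attr(hits, "params")
  ver <- as.character(utils::packageVersion("cnescan"))
  header <- c(paste0("#cnescan ", ver),
              if (!is.null(params))
                sprintf("#params: min_len=%d;max_len=%d;identity=%.6g;anchor_len=%s;min_chain_coverage=%d;ext_step=%d;merge_max_gap=%d",
                        params$min_len, params$max_len, params$identity,
                        if (is.null(params$anchor_len)) "auto"
                        else params$anchor_len,
                        params$min_chain_coverage, params$ext_step,
                        params$merge_max_gap),
              paste0("#", paste(hit_cols, collapse = "\t")))
  rows <- if (nrow(hits) > 0L)
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%d\t%d\t%d\t%.4f\t%s",
            hits$ref_name, hits$ref_start, hits$ref_end, hits$query_name,
            hits$query_start, hits$query_end, hits$ref_len, hits$query_len,
            hits$edit_distance, hits$identity, hits$query_strand)
  else character(0)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a CNE table written by [write_cnes()]
#'
#' @param path File written by [write_cnes()].
#' @return A hit data.frame (identity as stored, i.e. four decimals).
#' @export
read_cnes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != length(hit_cols)))
    stop("malformed CNE table: expected ", length(hit_cols), " columns")
  m <- do.call(rbind, f)
  out <- data.frame(
    ref_name = m[, 1L], ref_start = as.integer(m[, 2L]),
    ref_end = as.integer(m[, 3L]), query_name = m[, 4L],
    query_start = as.integer(m[, 5L]), query_end = as.integer(m[, 6L]),
    ref_len = as.integer(m[, 7L]), query_len = as.integer(m[, 8L]),
    edit_distance = as.integer(m[, 9L]), identity = as.numeric(m[, 10L]),
    query_strand = m[, 11L], stringsAsFactors = FALSE)
  out
}
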