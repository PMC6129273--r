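# Regions, masking and search-space selection. All coordinates handed to or
# returned by this module are 0-based half-open in source-sequence space;
# conversions from GFF3 (1-based inclusive) and BED (already 0-based
# half-open) happen here and nowhere else.

#' A coordinate-anchored DNA segment
#'
#' A region is a slice of a source sequence together with the coordinate of
#' its first base within that sequence, so that results computed on the slice
#' can be reported in source-sequence space.
#'
#' @param seq_name Name of the source sequence.
#' @param offset 0-based coordinate of the region's first base within the
#'   source sequence.
#' @param bases DNA string. Case is preserved (lowercase may carry soft-mask
#'   information consumed by [build_mask()]); discovery treats bases
#'   case-insensitively.
#' @return An object of class `"cne_region"`.
#' @export
region <- function(seq_name, offset, bases) {
  stopifnot(is.character(seq_name), length(seq_name) == 1L,
            is.character(bases), length(bases) == 1L)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L) stop("offset must be >= 0")
  structure(list(seq_name = seq_name, offset = offset, bases = bases),
            class = "cne_region")
}

#' @export
print.cne_region <- function(x, ...) {
  n <- nchar(x$bases)
  cat(sprintf("<cne_region> %s:[%d, %d) (%d bp)\n",
              x$seq_name, x$offset, x$offset + n, n))
  invisible(x)
}

as_region <- function(x, seq_name = "seq") {
  if (inherits(x, "cne_region")) return(x)
  if (is.character(x) && length(x) == 1L) {
    nm <- if (!is.null(names(x))) names(x) else seq_name
    return(region(nm, 0L, unname(x)))
  }
  stop("expected a cne_region or a single character string")
}

# import a GFF3/BED file unless a GRanges was passed directly
as_granges <- function(x, format) {
  if (is.null(x)) return(NULL)
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(format, " file not found: ", x)
    return(rtracklayer::import(x, format = format))
  }
  stop("expected a file path or a GRanges object")
}

#' Build a mask of exonic and repetitive positions
#'
#' Collects the intervals to be excluded from the CNE search: exon-typed
#' annotation features, repeat intervals, and (optionally) soft-masked
#' (lowercase) runs of the sequence itself. The three sources are merged into
#' one sorted, non-overlapping interval set in 0-based half-open
#' source-sequence coordinates.
#'
#' @param sequence The full source sequence (character scalar); used for
#'   soft-mask extraction and for clipping intervals to the sequence.
#' @param seq_name Name of the source sequence; features on other sequence
#'   names are skipped (with a warning for names outside `known_seqs`).
#' @param annotation GFF3 file path or `GRanges`; features whose `type` is in
#'   `exon_types` contribute intervals. GFF3 coordinates are 1-based
#'   inclusive and converted here.
#' @param repeats BED file path or `GRanges` of repeat intervals.
#' @param softmask Treat maximal lowercase runs of `sequence` as repeats
#'   (default `TRUE`; soft-masked assemblies encode simple and
#'   low-complexity repeats this way).
#' @param exon_types Annotation feature types counted as exonic.
#' @param known_seqs Sequence names that are expected to occur in the
#'   annotation besides `seq_name`; features on names outside this set
#'   trigger a warning before being skipped.
#' @return An object of class `"mask_track"`: the sequence name plus a
#'   two-column matrix of merged `(start, end)` intervals.
#' @export
build_mask <- function(sequence, seq_name, annotation = NULL, repeats = NULL,
                       softmask = TRUE, exon_types = c("exon", "CDS"),
                       known_seqs = seq_name) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_len <- nchar(sequence)
  starts <- integer(0)
  ends <- integer(0)

  take <- function(gr, keep_types = NULL) {
    sn <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(sn), c(seq_name, known_seqs))
    if (length(unknown) > 0L)
      warning("skipping features on unknown sequence(s): ",
              paste(unknown, collapse = ", "))
    gr <- gr[sn == seq_name]
    if (!is.null(keep_types)) {
      ty <- S4Vectors::mcols(gr)$type
      if (is.null(ty)) return(gr[0])
      gr <- gr[as.character(ty) %in% keep_types]
    }
    gr
  }

  gff <- as_granges(annotation, "gff3")
  if (!is.null(gff)) {
    ex <- take(gff, exon_types)
    starts <- c(starts, GenomicRanges::start(ex) - 1L)  # 1-based -> 0-based
    ends <- c(ends, GenomicRanges::end(ex))
  }
  bed <- as_granges(repeats, "bed")
  if (!is.null(bed)) {
    rp <- take(bed)
    starts <- c(starts, GenomicRanges::start(rp) - 1L)
    ends <- c(ends, GenomicRanges::end(rp))
  }
  if (isTRUE(softmask)) {
    m <- gregexpr("[a-z]+", sequence)[[1]]
    if (m[1] != -1L) {
      starts <- c(starts, as.integer(m) - 1L)
      ends <- c(ends, as.integer(m) - 1L + attr(m, "match.length"))
    }
  }

  if (length(starts) > 0L) {
    starts <- pmax(starts, 0L)
    ends <- pmin(ends, seq_len)
    keep <- ends > starts
    ir <- IRanges::reduce(IRanges::IRanges(start = starts[keep] + 1L,
                                           end = ends[keep]))
    iv <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  } else {
    iv <- cbind(start = integer(0), end = integer(0))
  }
  structure(list(seq_name = seq_name, intervals = iv), class = "mask_track")
}

#' @export
print.mask_track <- function(x, ...) {
  cat(sprintf("<mask_track> %s: %d interval(s), %d bp masked\n", x$seq_name,
              nrow(x$intervals), sum(x$intervals[, 2] - x$intervals[, 1])))
  invisible(x)
}

#' Replace masked positions of a region with N
#'
#' Masked positions become `'N'` so that they can never seed, extend or
#' silently inflate the identity of a match; the region's length and offset
#' are unchanged, keeping all downstream coordinates in source-sequence
#' space. Bases are uppercased. Idempotent.
#'
#' @param region A [region()].
#' @param mask A [build_mask()] result (intervals in source-sequence
#'   coordinates), or `NULL` for no masking.
#' @return A new `cne_region` of identical length and offset.
#' @export
apply_mask <- function(region, mask = NULL) {
  stopifnot(inherits(region, "cne_region"))
  b <- charToRaw(toupper(region$bases))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask_track"))
    if (mask$seq_name != region$seq_name)
      stop("mask is for sequence '", mask$seq_name, "', region is on '",
           region$seq_name, "'")
    n <- length(b)
    off <- region$offset
    iv <- mask$intervals
    for (k in seq_len(nrow(iv))) {
      a <- max(iv[k, 1L] - off, 0L)
      e <- min(iv[k, 2L] - off, n)
      if (e > a) b[(a + 1L):e] <- as.raw(78L)  # 'N'
    }
  }
  region(region$seq_name, region$offset, rawToChar(b))
}

#' Describe which part of the input to search
#'
#' @param mode `"whole"` (a full sequence record), `"range"` (an explicit
#'   0-based half-open coordinate slice) or `"gene"` (the window of `flank`
#'   bp on each side of a named gene, clamped to the sequence).
#' @param seq_name Sequence record to search (whole/range modes; optional for
#'   single-record input).
#' @param start,end 0-based half-open slice bounds (range mode).
#' @param gene Gene name or ID, matched against the `Name`, `ID`, `gene_name`
#'   and `gene_id` attributes of `gene`-typed annotation features.
#' @param flank Window half-width in bp around the gene (default 1e6).
#' @return An object of class `"search_request"`.
#' @export
search_request <- function(mode = c("whole", "range", "gene"),
                           seq_name = NULL, start = NULL, end = NULL,
                           gene = NULL, flank = 1000000L) {
  mode <- match.arg(mode)
  if (mode == "range") {
    if (is.null(start) || is.null(end)) stop("range mode needs start and end")
    start <- as.integer(start)
    end <- as.integer(end)
    if (is.na(start) || is.na(end) || start < 0L || start >= end)
      stop("range mode requires 0 <= start < end")
  }
  if (mode == "gene") {
    if (is.null(gene)) stop("gene mode needs a gene name")
    flank <- as.integer(flank)
    if (is.na(flank) || flank < 0L) stop("flank must be >= 0")
  }
  structure(list(mode = mode, seq_name = seq_name, start = start, end = end,
                 gene = gene, flank = flank), class = "search_request")
}

#' Carve the requested search region out of a sequence set
#'
#' @param fasta Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @param request A [search_request()].
#' @param annotation GFF3 path or `GRanges`; required for gene mode.
#' @return A [region()] anchored in source-sequence coordinates. Selection
#'   and masking are orthogonal: exons inside the returned region are only
#'   removed once [apply_mask()] is applied.
#' @export
select_region <- function(fasta, request, annotation = NULL) {
  stopifnot(inherits(request, "search_request"))
  if (methods::is(fasta, "XStringSet")) {
    nm <- vapply(strsplit(names(fasta), "\\s+"), `[`, "", 1L)
    fasta <- stats::setNames(as.character(fasta), nm)
  }
  stopifnot(is.character(fasta), !is.null(names(fasta)))

  pick_seq <- function(seq_name) {
    if (is.null(seq_name)) {
      if (length(fasta) != 1L)
        stop("seq_name must be given for multi-record input")
      return(names(fasta)[1L])
    }
    if (!seq_name %in% names(fasta))
      stop("sequence '", seq_name, "' not found in input (have: ",
           paste(names(fasta), collapse = ", "), ")")
    seq_name
  }

  if (request$mode == "whole") {
    sn <- pick_seq(request$seq_name)
    return(region(sn, 0L, fasta[[sn]]))
  }

  if (request$mode == "range") {
    sn <- pick_seq(request$seq_name)
    len <- nchar(fasta[[sn]])
    if (request$start >= len)
      stop("range start ", request$start, " is beyond the end of '", sn,
           "' (", len, " bp)")
    end <- min(request$end, len)
    return(region(sn, request$start,
                  substr(fasta[[sn]], request$start + 1L, end)))
  }

  # gene mode
  if (is.null(annotation))
    stop("gene mode requires a GFF3 annotation")
  gff <- as_granges(annotation, "gff3")
  ty <- S4Vectors::mcols(gff)$type
  genes <- if (is.null(ty)) gff[0] else gff[as.character(ty) == "gene"]
  mc <- S4Vectors::mcols(genes)
  name_of <- function(col) if (col %in% colnames(mc)) as.character(mc[[col]])
                           else rep(NA_character_, length(genes))
  labels <- cbind(name_of("Name"), name_of("ID"),
                  name_of("gene_name"), name_of("gene_id"))
  hit <- which(apply(labels == request$gene, 1L, any, na.rm = TRUE))
  if (length(hit) == 0L) {
    pool <- unique(stats::na.omit(as.vector(labels)))
    near <- agrep(request$gene, pool, max.distance = 0.25,
                  value = TRUE, ignore.case = TRUE)
    stop("gene '", request$gene, "' not found in annotation",
         if (length(near) > 0L)
           paste0("; did you mean: ", paste(utils::head(near, 5L),
                                            collapse = ", "), "?"))
  }
  if (length(hit) > 1L)
    stop("gene name '", request$gene, "' matches ", length(hit),
         " features; use an unambiguous ID")
  g <- genes[hit]
  sn <- pick_seq(as.character(GenomicRanges::seqnames(g)))
  len <- nchar(fasta[[sn]])
  from <- max(GenomicRanges::start(g) - 1L - request$flank, 0L)
  to <- min(GenomicRanges::end(g) + request$flank, len)
  region(sn, from, substr(fasta[[sn]], from + 1L, to))
}
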