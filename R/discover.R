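# The three-stage discovery algorithm: seed (maximal exact matches), merge
# (greedy co-linear chaining under an edit-distance gap cost), extend
# (threshold-bounded bidirectional growth). All anchor/chain coordinates are
# 0-based and local to the regions; reported hits are shifted into
# source-sequence space.

hit_cols <- c("ref_name", "ref_start", "ref_end", "query_name", "query_start",
              "query_end", "ref_len", "query_len", "edit_distance",
              "identity", "query_strand")

empty_hits <- function() {
  data.frame(ref_name = character(0), ref_start = integer(0),
             ref_end = integer(0), query_name = character(0),
             query_start = integer(0), query_end = integer(0),
             ref_len = integer(0), query_len = integer(0),
             edit_distance = integer(0), identity = numeric(0),
             query_strand = character(0), stringsAsFactors = FALSE)
}

#' Enumerate maximal exact matches between two regions
#'
#' Returns every triple `(ref_start, query_start, length)` with
#' `length >= l_min` such that the two substrings are identical, contain no
#' `N`, and cannot be extended by one position to the left or right in both
#' sequences simultaneously. Matches are proposed by a k-mer hash of the
#' reference and verified by direct base comparison, so the result is the
#' exact MEM set.
#'
#' @param x,y Reference and query: [region()] objects or plain strings.
#' @param l_min Minimum match length (bp), typically [min_anchor_length()].
#' @param threads Number of worker processes. The reference is scanned in
#'   blocks that partition the k-mer start positions, so the result is
#'   independent of `threads`; results are deduplicated and sorted either
#'   way.
#' @return A data.frame with integer columns `ref_start`, `query_start`,
#'   `length` (0-based, region-local), sorted by `(ref_start, query_start)`.
#' @examples
#' find_mems("ACGTACGT", "ACGT", 4) # matches at ref 0 and 4
#' @export
find_mems <- function(x, y, l_min, threads = 1L) {
  x <- as_region(x); y <- as_region(y)
  l_min <- as.integer(l_min)
  if (is.na(l_min) || l_min < 1L) stop("l_min must be >= 1")
  xb <- toupper(x$bases); yb <- toupper(y$bases)
  n <- nchar(xb)
  threads <- max(1L, as.integer(threads))

  if (threads == 1L || n < 4L * l_min * threads) {
    m <- cpp_find_mems(xb, yb, l_min, 0L, -1L)
  } else {
    cuts <- unique(as.integer(round(seq(0L, n, length.out = threads + 1L))))
    blocks <- Map(c, cuts[-length(cuts)], cuts[-1L])
    parts <- parallel::mclapply(blocks, function(bl)
      cpp_find_mems(xb, yb, l_min, bl[1L], bl[2L]), mc.cores = threads)
    m <- do.call(rbind, parts)
  }
  rs <- m[, 1L]; qs <- m[, 2L]; len <- m[, 3L]
  # dedup on (ref_start, query_start): a MEM is unique at its left end
  key <- as.numeric(rs) * (nchar(yb) + 1) + as.numeric(qs)
  keep <- !duplicated(key)
  o <- order(rs[keep], qs[keep])
  data.frame(ref_start = rs[keep][o], query_start = qs[keep][o],
             length = len[keep][o])
}

new_chain <- function(anchors, gap_edit) {
  structure(list(
    anchors = anchors,
    gap_edit = as.integer(gap_edit),
    ref_span = c(min(anchors$ref_start),
                 max(anchors$ref_start + anchors$length)),
    query_span = c(min(anchors$query_start),
                   max(anchors$query_start + anchors$length))),
    class = "cne_chain")
}

#' @export
print.cne_chain <- function(x, ...) {
  cat(sprintf("<cne_chain> %d anchor(s), ref [%d, %d), query [%d, %d), gap edit %d\n",
              nrow(x$anchors), x$ref_span[1], x$ref_span[2],
              x$query_span[1], x$query_span[2], x$gap_edit))
  invisible(x)
}

#' Merge anchors into co-linear chains
#'
#' Greedy left-to-right chaining of the anchor set. Consecutive anchors of a
#' chain are strictly co-linear and non-overlapping in both sequences, each
#' inter-anchor gap is at most `merge_max_gap` in both sequences, and merging
#' stops as soon as adding another gap would push the chain identity
#' `1 - gap_edit / max(span)` below the threshold `t` or a span beyond
#' `max_len`. The gap cost is the edit distance of the paired gap substrings.
#' Chains whose combined anchor length falls short of `min_chain_coverage`
#' are discarded. Each anchor is consumed by at most one chain; among
#' eligible successors the one minimising (ref gap + query gap) is taken,
#' ties broken on the smaller query start.
#'
#' @param anchors Anchor data.frame from [find_mems()] on the same `(x, y)`.
#' @inheritParams find_mems
#' @param params A [cne_params()] object.
#' @return A list of `cne_chain` objects.
#' @export
merge_anchors <- function(anchors, x, y, params) {
  stopifnot(inherits(params, "cne_params"),
            all(c("ref_start", "query_start", "length") %in% names(anchors)))
  x <- as_region(x); y <- as_region(y)
  if (nrow(anchors) == 0L) return(list())
  a <- anchors[order(anchors$ref_start, anchors$query_start), , drop = FALSE]
  res <- cpp_merge_anchors(toupper(x$bases), toupper(y$bases),
                           as.integer(a$ref_start),
                           as.integer(a$query_start),
                           as.integer(a$length),
                           params$identity, params$max_len,
                           params$merge_max_gap, params$min_chain_coverage)
  lapply(seq_along(res$gap_edit), function(ci) {
    new_chain(a[res$chain_id == ci - 1L, , drop = FALSE], res$gap_edit[ci])
  })
}

#' Extend a chain while the identity threshold allows
#'
#' Starting from the chain hull, both spans grow in windows of `ext_step`
#' bases per side. At each step the edit distances of the left and of the
#' right extension windows (reference window vs query window) are computed;
#' both sides are added if the estimated identity stays at or above `t`,
#' otherwise only the cheaper side. When even that would cross `t`, the
#' actual edit distance of the whole current element is recomputed (the
#' running estimate is an upper bound, so the identity can only be revised
#' upward) and extension continues accordingly. Extension halts when the
#' refreshed identity would still fall below `t`, when either element reaches
#' `max_len`, or when a sequence boundary or an `N` blocks both sides.
#'
#' @param chain A `cne_chain` from [merge_anchors()].
#' @inheritParams merge_anchors
#' @return A one-row hit data.frame (source-sequence coordinates, final edit
#'   distance and identity) if the final element pair has both lengths in
#'   `[min_len, max_len]` and identity `>= t`; otherwise `NULL`.
#' @export
extend_chain <- function(chain, x, y, params) {
  stopifnot(inherits(chain, "cne_chain"), inherits(params, "cne_params"))
  x <- as_region(x); y <- as_region(y)
  xb <- toupper(x$bases); yb <- toupper(y$bases)
  xn <- nchar(xb); yn <- nchar(yb)
  l <- params$min_len; u <- params$max_len
  t <- params$identity; w <- params$ext_step

  rs <- chain$ref_span[1L]; re <- chain$ref_span[2L]
  qs <- chain$query_span[1L]; qe <- chain$query_span[2L]
  D <- chain$gap_edit
  ok <- function(d, rl, ql) d <= (1 - t) * max(rl, ql) + 1e-9

  repeat {
    cap <- u - max(re - rs, qe - qs)
    if (cap <= 0L) break
    wl <- min(w, rs, qs, cap)
    if (wl > 0L && (substr(xb, rs, rs) == "N" || substr(yb, qs, qs) == "N"))
      wl <- 0L
    wr <- min(w, xn - re, yn - qe, cap)
    if (wr > 0L &&
        (substr(xb, re + 1L, re + 1L) == "N" ||
         substr(yb, qe + 1L, qe + 1L) == "N"))
      wr <- 0L
    if (wl == 0L && wr == 0L) break

    dl <- if (wl > 0L)
      cpp_edit_distance(substr(xb, rs - wl + 1L, rs),
                        substr(yb, qs - wl + 1L, qs)) else NA_integer_
    dr <- if (wr > 0L)
      cpp_edit_distance(substr(xb, re + 1L, re + wr),
                        substr(yb, qe + 1L, qe + wr)) else NA_integer_

    progressed <- FALSE
    if (wl > 0L && wr > 0L) {
      wrb <- min(wr, cap - wl)  # joint step may not overshoot max_len
      drb <- if (wrb == wr) dr
             else if (wrb > 0L)
               cpp_edit_distance(substr(xb, re + 1L, re + wrb),
                                 substr(yb, qe + 1L, qe + wrb)) else 0L
      if (ok(D + dl + drb, (re - rs) + wl + wrb, (qe - qs) + wl + wrb)) {
        rs <- rs - wl; qs <- qs - wl; re <- re + wrb; qe <- qe + wrb
        D <- D + dl + drb
        progressed <- TRUE
      }
    }
    if (!progressed) {
      go_left <- wl > 0L && (wr == 0L || dl <= dr)
      if (go_left) {
        if (ok(D + dl, (re - rs) + wl, (qe - qs) + wl)) {
          rs <- rs - wl; qs <- qs - wl; D <- D + dl
          progressed <- TRUE
        }
      } else if (ok(D + dr, (re - rs) + wr, (qe - qs) + wr)) {
        re <- re + wr; qe <- qe + wr; D <- D + dr
        progressed <- TRUE
      }
    }
    if (!progressed) {
      # the estimate would cross t: re-adjust it with the actual distance
      act <- cpp_edit_distance(substr(xb, rs + 1L, re),
                               substr(yb, qs + 1L, qe))
      if (act < D) D <- act else break
    }
  }

  rl <- re - rs; ql <- qe - qs
  d <- cpp_edit_distance(substr(xb, rs + 1L, re), substr(yb, qs + 1L, qe))
  id <- 1 - d / max(rl, ql)
  if (rl < l || ql < l || rl > u || ql > u || id < t - 1e-9) return(NULL)
  data.frame(ref_name = x$seq_name, ref_start = x$offset + rs,
             ref_end = x$offset + re, query_name = y$seq_name,
             query_start = y$offset + qs, query_end = y$offset + qe,
             ref_len = rl, query_len = ql, edit_distance = d, identity = id,
             query_strand = "+", stringsAsFactors = FALSE)
}

#' Collapse near-duplicate hits
#'
#' Hits whose reference intervals and query intervals each reciprocally
#' overlap by more than 50% (on the same sequences and strand) are grouped
#' transitively; one representative per group survives: highest identity,
#' then longest reference span, then smallest reference start. Output is
#' sorted by `(ref_name, ref_start)`.
#'
#' @param hits A hit data.frame.
#' @return The deduplicated, sorted hit data.frame.
#' @export
dedup_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  recip <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2)
    ov > 0.5 * (e1 - s1) && ov > 0.5 * (e2 - s2)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hits$ref_name[i] != hits$ref_name[j] ||
        hits$query_name[i] != hits$query_name[j] ||
        hits$query_strand[i] != hits$query_strand[j]) next
    if (recip(hits$ref_start[i], hits$ref_end[i],
              hits$ref_start[j], hits$ref_end[j]) &&
        recip(hits$query_start[i], hits$query_end[i],
              hits$query_start[j], hits$query_end[j]))
      parent[find(j)] <- find(i)
  }
  grp <- vapply(seq_len(n), find, 0L)
  keep <- vapply(split(seq_len(n), grp), function(ix) {
    o <- order(-hits$identity[ix], -(hits$ref_end[ix] - hits$ref_start[ix]),
               hits$ref_start[ix])
    ix[o[1L]]
  }, 0L)
  out <- hits[sort(keep), , drop = FALSE]
  out <- out[order(out$ref_name, out$ref_start, out$query_name,
                   out$query_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

revcomp_dna <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Discover conserved non-coding elements between two regions
#'
#' Runs the full three-stage pipeline: maximal exact matches of length
#' [min_anchor_length()] are enumerated, merged into co-linear chains, and
#' extended while the identity threshold allows; the surviving element pairs
#' are deduplicated. Every returned hit is independently re-verifiable:
#' recomputing the identity of its two substrings yields at least `t` and
#' both lengths lie in `[min_len, max_len]`.
#'
#' @inheritParams merge_anchors
#' @param threads Worker count for the seeding stage; the output is
#'   independent of it.
#' @param revcomp Additionally search the reverse complement of `y` and
#'   report such hits with `query_strand == "-"` (off by default).
#' @param verbose Emit per-stage progress messages.
#' @return A hit data.frame (class `"cne_hits"`), sorted by
#'   `(ref_name, ref_start)`, with the [cne_params()] attached as attribute
#'   `"params"`.
#' @examples
#' p <- cne_params(8, 50, 0.9, min_chain_coverage = 8)
#' discover_cnes("AAACCCGGGTTTACGTACGT", "CCCGGGTTTACG", p)
#' @export
discover_cnes <- function(x, y, params, threads = 1L, revcomp = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(params, "cne_params"))
  x <- as_region(x, "ref"); y <- as_region(y, "query")
  lmin <- min_anchor_length(params)
  say <- function(...) if (isTRUE(verbose)) message(...)

  one_pass <- function(yr) {
    anchors <- find_mems(x, yr, lmin, threads = threads)
    say("anchors found: ", nrow(anchors), " (minimum length ", lmin, ")")
    chains <- merge_anchors(anchors, x, yr, params)
    say("chains kept: ", length(chains))
    hits <- lapply(chains, extend_chain, x = x, y = yr, params = params)
    hits <- do.call(rbind, hits)
    if (is.null(hits)) empty_hits() else hits
  }

  hits <- one_pass(y)
  if (isTRUE(revcomp)) {
    yl <- nchar(y$bases)
    yr <- region(y$seq_name, 0L, revcomp_dna(y$bases))
    h2 <- one_pass(yr)
    if (nrow(h2) > 0L) {
      # map reverse-complement coordinates back to the original query strand
      qs <- yl - h2$query_end
      qe <- yl - h2$query_start
      h2$query_start <- y$offset + qs
      h2$query_end <- y$offset + qe
      h2$query_strand <- "-"
    }
    hits <- rbind(hits, h2)
  }
  out <- dedup_hits(hits)
  say("hits reported: ", nrow(out))
  class(out) <- c("cne_hits", "data.frame")
  attr(out, "params") <- params
  out
}

#' @export
print.cne_hits <- function(x, ...) {
  p <- attr(x, "params")
  if (!is.null(p))
    cat(sprintf("CNE hits: %d element pair(s) (l in [%d, %d], t = %.4f)\n",
                nrow(x), p$min_len, p$max_len, p$identity))
  NextMethod()
}
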