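# Seeded synthetic-data generator: random DNA backgrounds with planted,
# divergence-controlled homologous segment pairs (plus decoys above the
# divergence budget and fake exon annotation), and the recovery scorer used
# to evaluate pipeline output against the planted truth.

#' Specification of a synthetic reference/query pair
#'
#' The defaults describe the standard validation scenario: a 1 Mbp reference
#' and a 0.5 Mbp query with human-like GC, 50 planted conserved elements of
#' 200-500 bp at 2% divergence, and 10 decoy segments at 20% divergence
#' (well above the identity budget of a t = 0.9 search, so a correct pipeline
#' must not report them).
#'
#' @param ref_len,query_len Background lengths in bp.
#' @param gc GC fraction of the background (default 0.41, human-like).
#' @param n_cne Number of planted conserved element pairs.
#' @param cne_len_range Length range (bp) of planted segments (and decoys).
#' @param divergence Per-base mutation rate applied to each planted copy;
#'   exactly `ceiling(divergence * length)` mutations are placed at distinct
#'   positions and substitutions always change the base, so the realised
#'   divergence is exact rather than binomially noisy.
#' @param indel_fraction Share of mutations that are 1-bp indels
#'   (default 0.1).
#' @param n_decoys Number of decoy segment pairs.
#' @param decoy_divergence Mutation rate of decoys; must exceed `divergence`.
#' @param exon_density Fraction of the reference covered by fake exon
#'   features (emitted as GFF3 over non-planted intervals).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(ref_len = 1000000L, query_len = 500000L, gc = 0.41,
                       n_cne = 50L, cne_len_range = c(200L, 500L),
                       divergence = 0.02, indel_fraction = 0.1,
                       n_decoys = 10L, decoy_divergence = 0.2,
                       exon_density = 0.02, seed = 42L) {
  stopifnot(ref_len >= 1, query_len >= 1, gc > 0, gc < 1,
            n_cne >= 0, n_decoys >= 0,
            length(cne_len_range) == 2L,
            cne_len_range[1] >= 1, cne_len_range[1] <= cne_len_range[2],
            divergence >= 0, divergence < 1,
            indel_fraction >= 0, indel_fraction <= 1,
            decoy_divergence > divergence, decoy_divergence < 1,
            exon_density >= 0, exon_density < 1)
  structure(list(ref_len = as.integer(ref_len),
                 query_len = as.integer(query_len), gc = gc,
                 n_cne = as.integer(n_cne),
                 cne_len_range = as.integer(cne_len_range),
                 divergence = divergence, indel_fraction = indel_fraction,
                 n_decoys = as.integer(n_decoys),
                 decoy_divergence = decoy_divergence,
                 exon_density = exon_density, seed = as.integer(seed)),
            class = "synth_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# non-overlapping interval placement by rejection sampling
place_intervals <- function(total_len, lengths, occupied = NULL) {
  starts <- integer(length(lengths))
  acc_s <- if (is.null(occupied)) integer(0) else occupied[, 1L]
  acc_e <- if (is.null(occupied)) integer(0) else occupied[, 2L]
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    if (total_len < len)
      stop("cannot place a ", len, " bp interval in ", total_len,
           " bp; use longer sequences")
    placed <- FALSE
    for (try in 1:1000) {
      s <- sample.int(total_len - len + 1L, 1L) - 1L
      if (!any(s < acc_e & s + len > acc_s)) {
        starts[i] <- s
        acc_s <- c(acc_s, s)
        acc_e <- c(acc_e, s + len)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", length(lengths), " non-overlapping ",
           "intervals; use longer sequences or fewer/shorter elements")
  }
  starts
}

# apply exactly ceiling(rate * nchar) mutations at distinct positions;
# substitutions always change the base, indels are single-base
mutate_segment <- function(seq, rate, indel_fraction) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  n_mut <- as.integer(ceiling(rate * n))
  if (n_mut == 0L)
    return(list(seq = seq, n_sub = 0L, n_indel = 0L))
  n_mut <- min(n_mut, n)
  pos <- sample.int(n, n_mut)
  n_indel <- as.integer(round(indel_fraction * n_mut))
  is_indel <- seq_along(pos) <= n_indel  # pos is already a random draw
  bases <- c("A", "C", "G", "T")
  for (k in order(pos, decreasing = TRUE)) {
    p <- pos[k]
    if (is_indel[k]) {
      if (runif(1) < 0.5) {
        v <- v[-p]                                   # deletion
      } else {
        v <- append(v, sample(bases, 1L), after = p) # insertion
      }
    } else {
      v[p] <- sample(setdiff(bases, v[p]), 1L)       # substitution
    }
  }
  list(seq = paste(v, collapse = ""), n_sub = n_mut - n_indel,
       n_indel = n_indel)
}

#' Generate a reference/query pair with planted conserved elements
#'
#' Draws two independent random backgrounds, copies `n_cne` reference
#' segments into the query with exactly `ceiling(divergence * length)`
#' mutations each, plants `n_decoys` additional copies at
#' `decoy_divergence`, and annotates non-planted reference intervals with
#' fake exon features up to `exon_density`. All planted intervals are
#' mutually non-overlapping within each sequence. Fully reproducible from
#' `spec$seed` (the caller's RNG state is restored on exit).
#'
#' @param spec A [synth_spec()].
#' @param dir Optional directory; when given, `ref.fa`, `query.fa`,
#'   `exons.gff3` and `truth.tsv` are written there.
#' @return A list with `ref` and `query` (named character vectors), `truth`
#'   (data.frame: ref/query intervals, type `"cne"`/`"decoy"`, mutation
#'   counts and realised identity), `exons` (data.frame of 0-based half-open
#'   exon intervals), `spec`, and (if `dir` was given) `paths`.
#' @export
generate_pair <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  ref <- random_dna(spec$ref_len, spec$gc)
  n_el <- spec$n_cne + spec$n_decoys
  lens <- if (n_el > 0L)
    sample(seq(spec$cne_len_range[1L], spec$cne_len_range[2L]), n_el,
           replace = TRUE) else integer(0)
  ref_starts <- place_intervals(spec$ref_len, lens)

  seg <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    src <- substr(ref, ref_starts[i] + 1L, ref_starts[i] + lens[i])
    rate <- if (i <= spec$n_cne) spec$divergence else spec$decoy_divergence
    seg[[i]] <- mutate_segment(src, rate, spec$indel_fraction)
  }
  mut_lens <- vapply(seg, function(s) nchar(s$seq), 0L)
  query_starts <- place_intervals(spec$query_len, mut_lens)

  # splice mutated segments into the query background
  qbg <- random_dna(spec$query_len, spec$gc)
  if (n_el > 0L) {
    o <- order(query_starts)
    pieces <- character(0)
    at <- 0L
    for (i in o) {
      pieces <- c(pieces, substr(qbg, at + 1L, query_starts[i]), seg[[i]]$seq)
      at <- query_starts[i] + mut_lens[i]
    }
    query <- paste(c(pieces, substr(qbg, at + 1L, spec$query_len)),
                   collapse = "")
  } else {
    query <- qbg
  }

  truth <- data.frame(
    ref_name = rep("ref1", n_el),
    ref_start = ref_starts, ref_end = ref_starts + lens,
    query_name = rep("query1", n_el),
    query_start = query_starts, query_end = query_starts + mut_lens,
    type = rep(c("cne", "decoy"), c(spec$n_cne, spec$n_decoys)),
    n_substitutions = vapply(seg, `[[`, 0L, "n_sub"),
    n_indels = vapply(seg, `[[`, 0L, "n_indel"),
    stringsAsFactors = FALSE)
  truth$realized_identity <- if (n_el > 0L)
    1 - (truth$n_substitutions + truth$n_indels) / pmax(lens, mut_lens)
  else numeric(0)

  # fake exon features over non-planted reference intervals
  exon_target <- floor(spec$exon_density * spec$ref_len)
  exon_s <- integer(0); exon_e <- integer(0)
  occupied <- cbind(ref_starts, ref_starts + lens)
  covered <- 0L
  while (covered < exon_target) {
    elen <- sample(100:300, 1L)
    s <- tryCatch(place_intervals(spec$ref_len, elen, occupied),
                  error = function(e) NULL)
    if (is.null(s)) break
    occupied <- rbind(occupied, c(s, s + elen))
    exon_s <- c(exon_s, s); exon_e <- c(exon_e, s + elen)
    covered <- covered + elen
  }
  exons <- data.frame(seq_name = rep("ref1", length(exon_s)),
                      start = exon_s, end = exon_e,
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  out <- list(ref = c(ref1 = ref), query = c(query1 = query),
              truth = truth, exons = exons, spec = spec)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(ref = file.path(dir, "ref.fa"),
                  query = file.path(dir, "query.fa"),
                  exons = file.path(dir, "exons.gff3"),
                  truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(out$ref), paths$ref)
    Biostrings::writeXStringSet(Biostrings::BStringSet(out$query),
                                paths$query)
    if (nrow(exons) > 0L) {
      gr <- GenomicRanges::GRanges(
        seqnames = exons$seq_name,
        ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
        type = "exon", ID = sprintf("exon%04d", seq_len(nrow(exons))))
      rtracklayer::export(gr, paths$exons, format = "gff3")
    } else {
      writeLines("##gff-version 3", paths$exons)
    }
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Score pipeline output against a planted truth table
#'
#' A truth element counts as recovered when some hit overlaps both its
#' reference interval and its query interval reciprocally by at least
#' `min_overlap` (overlap divided by each interval's length). Hits that
#' recover no element are split into decoy hits (reciprocal overlap with a
#' decoy pair) and false-positive candidates.
#'
#' @param hits Hit data.frame (e.g. from [discover_cnes()]).
#' @param truth Truth table from [generate_pair()] (same coordinate space).
#' @param min_overlap Reciprocal overlap threshold (default 0.8).
#' @return An object of class `"recovery_report"`: sensitivity, the mean
#'   nucleotide-overlap percentage of matched pairs, per-element detail, and
#'   hit classification counts.
#' @export
score_recovery <- function(hits, truth, min_overlap = 0.8) {
  pair_recip <- function(h, tr) {
    ov_r <- min(h$ref_end, tr$ref_end) - max(h$ref_start, tr$ref_start)
    ov_q <- min(h$query_end, tr$query_end) - max(h$query_start, tr$query_start)
    if (h$ref_name != tr$ref_name || h$query_name != tr$query_name ||
        ov_r <= 0 || ov_q <= 0) return(NULL)
    list(ok = ov_r >= min_overlap * (h$ref_end - h$ref_start) &&
              ov_r >= min_overlap * (tr$ref_end - tr$ref_start) &&
              ov_q >= min_overlap * (h$query_end - h$query_start) &&
              ov_q >= min_overlap * (tr$query_end - tr$query_start),
         pct = 50 * (ov_r / (tr$ref_end - tr$ref_start) +
                     ov_q / (tr$query_end - tr$query_start)))
  }

  n_hits <- if (is.null(hits)) 0L else nrow(hits)
  hit_matched <- rep(FALSE, n_hits)
  hit_decoy <- rep(FALSE, n_hits)

  score_rows <- function(rows) {
    recovered <- logical(nrow(rows))
    overlap_pct <- rep(NA_real_, nrow(rows))
    for (i in seq_len(nrow(rows))) {
      best <- NA_real_
      for (j in seq_len(n_hits)) {
        r <- pair_recip(hits[j, ], rows[i, ])
        if (is.null(r) || !r$ok) next
        recovered[i] <- TRUE
        if (rows$type[i] == "cne") hit_matched[j] <<- TRUE
        else hit_decoy[j] <<- TRUE
        if (is.na(best) || r$pct > best) best <- r$pct
      }
      overlap_pct[i] <- best
    }
    data.frame(recovered = recovered, overlap_pct = overlap_pct)
  }

  cne <- truth[truth$type == "cne", , drop = FALSE]
  dec <- truth[truth$type == "decoy", , drop = FALSE]
  sc <- score_rows(cne)
  if (nrow(dec) > 0L) score_rows(dec)

  per_truth <- cbind(cne[, c("ref_name", "ref_start", "ref_end",
                             "query_name", "query_start", "query_end")], sc)
  structure(list(
    sensitivity = if (nrow(cne) > 0L) mean(sc$recovered) else NA_real_,
    mean_overlap_pct = if (any(sc$recovered))
      mean(sc$overlap_pct[sc$recovered]) else NA_real_,
    n_truth = nrow(cne),
    n_recovered = sum(sc$recovered),
    n_hits = n_hits,
    n_matched_hits = sum(hit_matched),
    n_decoy_hits = sum(hit_decoy & !hit_matched),
    n_unmatched_hits = sum(!hit_matched & !hit_decoy),
    min_overlap = min_overlap,
    per_truth = per_truth), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Planted-element recovery\n")
  cat(sprintf("  sensitivity        : %.3f (%d / %d at reciprocal overlap >= %.2f)\n",
              x$sensitivity, x$n_recovered, x$n_truth, x$min_overlap))
  cat(sprintf("  mean overlap       : %.2f%% of planted nucleotides\n",
              x$mean_overlap_pct))
  cat(sprintf("  hits               : %d (%d matched, %d decoy, %d unmatched)\n",
              x$n_hits, x$n_matched_hits, x$n_decoy_hits, x$n_unmatched_hits))
  invisible(x)
}
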