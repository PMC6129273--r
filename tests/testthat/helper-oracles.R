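# Independent oracles used across the suite. These deliberately share no code
# with the package internals: the edit-distance oracle is the quadratic
# dynamic-programming recurrence, the MEM oracle enumerates maximal runs on
# every diagonal of the full comparison matrix.

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# quadratic DP for unit-cost edit distance; 'N' (or anything non-ACGT)
# matches nothing. Rows are vectorised; the insertion recurrence
# cur[j] = min(cand[j], cur[j-1] + 1) is resolved with a running minimum.
dp_edit <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  m <- length(av); n <- length(bv)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  acgt <- c("A", "C", "G", "T")
  prev <- 0:n
  for (i in seq_len(m)) {
    subc <- ifelse(bv == av[i] & av[i] %in% acgt & bv %in% acgt, 0L, 1L)
    cand <- pmin(prev[1:n] + subc, prev[2:(n + 1L)] + 1L)
    base <- c(i, cand)
    g <- cummin(base - 0:n)
    prev <- g + 0:n
  }
  prev[n + 1L]
}

# brute-force MEM enumeration: maximal equal runs along every diagonal
mem_oracle <- function(x, y, lmin) {
  xv <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  yv <- strsplit(toupper(y), "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  xv[!xv %in% acgt] <- "!"  # never equal across sequences
  yv[!yv %in% acgt] <- "?"
  n <- length(xv); m <- length(yv)
  out <- list()
  if (n >= lmin && m >= lmin && lmin >= 1L) {
    for (d in (-(m - 1L)):(n - 1L)) {
      i0 <- max(d, 0L); j0 <- i0 - d
      len <- min(n - i0, m - j0)
      if (len < lmin) next
      eq <- xv[(i0 + 1L):(i0 + len)] == yv[(j0 + 1L):(j0 + len)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values & r$lengths >= lmin
      if (any(keep))
        out[[length(out) + 1L]] <-
          cbind(i0 + starts[keep], j0 + starts[keep], r$lengths[keep])
    }
  }
  if (length(out) == 0L)
    return(data.frame(ref_start = integer(0), query_start = integer(0),
                      length = integer(0)))
  mm <- do.call(rbind, out)
  o <- order(mm[, 1L], mm[, 2L])
  data.frame(ref_start = mm[o, 1L], query_start = mm[o, 2L],
             length = mm[o, 3L])
}

# plant exactly n_edits unit edits (substitutions and 1-bp indels) at
# distinct positions of a copy of seq; independent of the package generator
plant_edits <- function(seq, n_edits, indel_fraction = 0.2) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (n_edits == 0L) return(seq)
  pos <- sample.int(length(v), n_edits)
  n_indel <- floor(indel_fraction * n_edits)
  is_indel <- seq_along(pos) <= n_indel
  bases <- c("A", "C", "G", "T")
  for (k in order(pos, decreasing = TRUE)) {
    p <- pos[k]
    if (is_indel[k]) {
      if (runif(1) < 0.5) v <- v[-p]
      else v <- append(v, sample(bases, 1L), after = p)
    } else {
      v[p] <- sample(setdiff(bases, v[p]), 1L)
    }
  }
  paste(v, collapse = "")
}

# extract the two substrings of a hit from the raw source sequences
hit_substrings <- function(hit, ref, query) {
  list(ref = substr(ref[[hit$ref_name]], hit$ref_start + 1L, hit$ref_end),
       query = substr(query[[hit$query_name]], hit$query_start + 1L,
                      hit$query_end))
}
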