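#' Search criteria for CNE discovery
#'
#' Bundles the user-facing thresholds that drive every stage of the
#' seed-merge-extend pipeline.
#'
#' @param min_len Lower bound \eqn{\ell} (bp) on the length of reported
#'   elements.
#' @param max_len Upper bound \eqn{u} (bp) on the length of either reported
#'   element. Extension halts as soon as one of the two elements reaches
#'   `max_len`.
#' @param identity Relative identity threshold \eqn{t \in (0,1]}:
#'   `1 - edit_distance / max(length)` of a reported pair must be at least
#'   `identity`. `identity = 1` reports identical substrings only.
#' @param anchor_len Optional explicit minimum anchor (maximal exact match)
#'   length. When supplied, the maximum of this value and the computed
#'   minimum anchor length is used (see [min_anchor_length()]).
#' @param min_chain_coverage Minimum combined anchor length (bp) a chain must
#'   reach before it is extended. Defaults to `floor(min_len / 2)`.
#' @param ext_step Extension window width \eqn{w} (bp) added per side and per
#'   iteration during the extension stage. Default 5.
#' @param merge_max_gap Maximum gap (bp), in either sequence, bridged between
#'   two consecutive anchors of a chain. Defaults to `min_len`.
#'
#' @return An object of class `"cne_params"`.
#' @examples
#' p <- cne_params(200, 500, 0.9)
#' min_anchor_length(p)
#' @export
cne_params <- function(min_len, max_len, identity, anchor_len = NULL,
                       min_chain_coverage = NULL, ext_step = 5L,
                       merge_max_gap = NULL) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(min_len) || min_len < 1L)
    stop("min_len must be an integer >= 1")
  if (is.na(max_len) || max_len < min_len)
    stop("max_len must be an integer >= min_len")
  if (!is.numeric(identity) || length(identity) != 1L ||
      is.na(identity) || identity <= 0 || identity > 1)
    stop("identity threshold must lie in (0, 1]")
  if (!is.null(anchor_len)) {
    anchor_len <- as.integer(anchor_len)
    if (is.na(anchor_len) || anchor_len < 1L)
      stop("anchor_len must be an integer >= 1")
  }
  if (is.null(min_chain_coverage)) min_chain_coverage <- min_len %/% 2L
  min_chain_coverage <- max(1L, as.integer(min_chain_coverage))
  ext_step <- as.integer(ext_step)
  if (is.na(ext_step) || ext_step < 1L) stop("ext_step must be >= 1")
  if (is.null(merge_max_gap)) merge_max_gap <- min_len
  merge_max_gap <- as.integer(merge_max_gap)
  if (is.na(merge_max_gap) || merge_max_gap < 1L)
    stop("merge_max_gap must be >= 1")
  structure(
    list(min_len = min_len, max_len = max_len, identity = identity,
         anchor_len = anchor_len, min_chain_coverage = min_chain_coverage,
         ext_step = ext_step, merge_max_gap = merge_max_gap),
    class = "cne_params")
}

#' @export
print.cne_params <- function(x, ...) {
  cat("CNE search parameters\n")
  cat(sprintf("  length bounds   : [%d, %d] bp\n", x$min_len, x$max_len))
  cat(sprintf("  identity t      : %.4f\n", x$identity))
  cat(sprintf("  anchor length   : %s (computed minimum %d)\n",
              if (is.null(x$anchor_len)) "auto" else x$anchor_len,
              min_anchor_length(x)))
  cat(sprintf("  chain coverage  : >= %d bp\n", x$min_chain_coverage))
  cat(sprintf("  merge max gap   : %d bp\n", x$merge_max_gap))
  cat(sprintf("  extension step  : %d bp\n", x$ext_step))
  invisible(x)
}

#' Minimum anchor length implied by the length and identity thresholds
#'
#' Two elements of length at least \eqn{\ell} whose edit distance does not
#' exceed the budget \eqn{e = \lfloor \ell - t\ell \rfloor} must, by a
#' counting (pigeonhole) argument, share an exact run of length at least
#' \eqn{\lfloor \ell / (e + 1) \rfloor}. Maximal exact matches at least this
#' long are therefore guaranteed to seed every reportable element. When the
#' user supplies an explicit anchor length, the maximum of the two values is
#' used.
#'
#' @param params A [cne_params()] object.
#' @return Integer minimum anchor length (>= 1).
#' @examples
#' min_anchor_length(cne_params(200, 500, 0.95)) # 18
#' @export
min_anchor_length <- function(params) {
  stopifnot(inherits(params, "cne_params"))
  l <- params$min_len
  # edit budget: integral number of operations; small fuzz guards against
  # binary-representation artefacts such as 200 * 0.05 = 10.000000000000002
  e <- as.integer(floor(l * (1 - params$identity) + 1e-9))
  bound <- l %/% (e + 1L)
  user <- if (is.null(params$anchor_len)) 0L else params$anchor_len
  max(bound, user, 1L)
}

#' Unit-cost edit distance between two DNA strings
#'
#' Minimum number of single-base insertions, deletions and substitutions
#' transforming `a` into `b` (simple edit distance), computed with Myers'
#' bit-vector algorithm. Input is uppercased first. `N` (and any base other
#' than A/C/G/T) matches nothing -- not even another `N` -- so masked bases
#' always cost one edit against any letter.
#'
#' @param a,b Character scalars over the DNA alphabet (possibly empty).
#' @return Integer edit distance.
#' @examples
#' edit_distance("ACGT", "ACGT") # 0
#' edit_distance("", "ACG")      # 3
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, !is.na(a),
            is.character(b), length(b) == 1L, !is.na(b))
  cpp_edit_distance(toupper(a), toupper(b))
}

#' Relative identity score of two DNA strings
#'
#' `1 - edit_distance(a, b) / max(nchar(a), nchar(b))`. The denominator is
#' the longer of the two strings, so length asymmetry introduced by indels is
#' penalised and the score always lies in `[0, 1]`; it equals 1 exactly when
#' the (N-free) strings are identical.
#'
#' @inheritParams edit_distance
#' @return Numeric identity in `[0, 1]`.
#' @examples
#' identity_score("ACGT", "ACGA") # 0.75
#' @export
identity_score <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, !is.na(a),
            is.character(b), length(b) == 1L, !is.na(b))
  n <- max(nchar(a), nchar(b))
  if (n == 0L) stop("identity score is undefined for two empty strings")
  1 - edit_distance(a, b) / n
}
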