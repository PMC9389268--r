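#' Hypergeometric upper tail
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, M, n)}: the chance of
#' drawing at least k annotated genes when n genes are drawn without
#' replacement from a background of N genes of which M carry the
#' annotation.  Computed through \code{stats::phyper}, which works in log
#' space internally and is stable for extreme tails.
#'
#' @param k observed hits in the study set (vectorized).
#' @param n study set size.
#' @param M annotated genes in the background.
#' @param N background size.
#' @return upper-tail probability in [0, 1].
#' @examples
#' hypergeomTail(0, 5, 5, 10)   # 1
#' hypergeomTail(5, 5, 5, 10)   # 1/choose(10, 5)
#' @export
hypergeomTail <- function(k, n, M, N) {
  len <- max(length(k), length(n), length(M), length(N))
  k <- rep_len(k, len); n <- rep_len(n, len)
  M <- rep_len(M, len); N <- rep_len(N, len)
  bad <- k < 0 | n < 0 | M < 0 | N < 1 | k > n | k > M | n > N | M > N
  if (any(bad))
    .stopf("argument",
           "need 0 <= k <= min(n, M), n <= N, M <= N (violated at index %d)",
           which(bad)[1L])
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term over-representation by the hypergeometric test
#'
#' For each term with at least \code{minTermSize} annotated genes inside
#' the background, tests whether the study set contains more of the term's
#' genes than expected under random draws from the background.  Study genes
#' must be a subset of the background; annotation genes outside the
#' background are dropped (a message reports how many).  q-values are BH
#' over the reported terms; rows are sorted by p then term id, a
#' deterministic order.
#'
#' @param study character vector of study gene ids (e.g. one inheritance
#'   category's DEGs).
#' @param background character vector of background gene ids (typically the
#'   expressed genes), a superset of \code{study}.
#' @param annotation a [TermAnnotation-class].
#' @param minTermSize smallest in-background term size tested (default 2).
#' @return data.frame with columns term_id, term_name, k, n, M, N, fold
#'   (= (k/n)/(M/N)), p, q.
#' @export
enrichTerms <- function(study, background, annotation, minTermSize = 2) {
  stopifnot(is(annotation, "TermAnnotation"))
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (!length(study)) .stopf("argument", "study set is empty")
  outside <- setdiff(study, background)
  if (length(outside))
    .stopf("argument", "%d study gene(s) not in the background, e.g. %s",
           length(outside), outside[1L])
  sets <- geneSets(annotation)
  annUniverse <- unique(unlist(sets))
  nDropped <- length(setdiff(annUniverse, background))
  if (nDropped)
    message(nDropped, " annotated gene(s) outside the background were dropped")
  sets <- lapply(sets, intersect, background)
  keep <- lengths(sets) >= minTermSize
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), M = integer(0),
                      N = integer(0), fold = numeric(0), p = numeric(0),
                      q = numeric(0)))
  N <- length(background); n <- length(study)
  M <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, study)), 1L)
  stopifnot(all(M <= N), all(n <= N))   # restriction can never break bounds
  p <- hypergeomTail(k, n, M, N)
  out <- data.frame(term_id = names(sets),
                    term_name = unname(termNames(annotation)[names(sets)]),
                    k = k, n = n, M = M, N = N,
                    fold = (k / n) / (M / N), p = p,
                    row.names = NULL)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}
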