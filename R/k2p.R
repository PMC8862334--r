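#' Kimura two-parameter distance between two aligned sequences
#'
#' With `P` the transition fraction and `Q` the transversion fraction over
#' comparable columns (pairwise deletion of `N`/`-`/ambiguities),
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Used to judge whether the
#' divergence range of a candidate reference taxon brackets the divergences
#' in a focal complex.
#'
#' @param seq1,seq2 character vectors of single residues, equal length.
#' @return numeric distance (substitutions/site).
#' @export
k2p_distance <- function(seq1, seq2) {
  if (length(seq1) != length(seq2)) stop("sequences must be aligned (equal length)")
  x <- match(toupper(seq1), BASES)
  y <- match(toupper(seq2), BASES)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L) stop("no comparable column after pairwise deletion")
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  # purine A(1)/G(3), pyrimidine C(2)/T(4): transition iff same parity
  ts <- diff & ((x %% 2L) == (y %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop("saturated distance: 1-2P-Q or 1-2Q not positive")
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Summary of K2P distances across a dataset
#'
#' Aggregates per-locus K2P distances over sample pairs, either across all
#' pairs or restricted to pairs of samples labeled as different species.
#' Pairs whose distance is saturated at a locus are excluded from that locus
#' with a warning.
#'
#' @param ds a [multilocus_dataset]; `scope = "between-species"` requires a
#'   species column in the sample map.
#' @param scope `"all-pairs"` or `"between-species"`.
#' @return named numeric vector `c(mean, min, max)` in percent
#'   (substitutions per 100 sites).
#' @export
k2p_summary <- function(ds, scope = c("all-pairs", "between-species")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ds, "multilocus_dataset"))
  if (!length(ds$loci)) stop("dataset has no loci")
  sm <- ds$sample_map
  if (scope == "between-species" && !"species" %in% names(sm))
    stop("between-species scope needs a species column in the sample map")
  sp_of <- if ("species" %in% names(sm)) stats::setNames(sm$species, sm$sample)
  d <- numeric(0)
  n_sat <- 0L
  for (sq in ds$loci) {
    ids <- rownames(sq)
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      if (scope == "between-species" && sp_of[[ids[i]]] == sp_of[[ids[j]]]) next
      val <- tryCatch(k2p_distance(sq[i, ], sq[j, ]),
                      error = function(e) NA_real_)
      if (is.na(val)) n_sat <- n_sat + 1L else d <- c(d, val)
    }
  }
  if (n_sat > 0L)
    warning(n_sat, " saturated/incomparable pair-locus distance(s) excluded")
  if (!length(d)) stop("no computable pairwise distance in scope '", scope, "'")
  c(mean = mean(d), min = min(d), max = max(d)) * 100
}
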