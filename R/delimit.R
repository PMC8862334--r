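#' Classify every population pair of a focal dataset
#'
#' Computes the feature vector of each unordered population pair, scales it
#' with the model's stored transform, and returns the predicted label and
#' calibrated same-species probability. The dataset should be
#' complete-matrix filtered first; the feature configuration must match the
#' model's fingerprint.
#'
#' @param model a `delim_model`.
#' @param ds a [multilocus_dataset] with >= 2 populations.
#' @param cfg the [feature_config] used for the features.
#' @return data frame of class `pair_classification` with columns `popA`,
#'   `popB` (lexicographic, `popA < popB`), `label` (-1 iff
#'   `p_same >= 0.5`) and `p_same`.
#' @export
classify_pairs <- function(model, ds, cfg = feature_config()) {
  stopifnot(inherits(model, "delim_model"), inherits(ds, "multilocus_dataset"))
  if (!identical(config_fingerprint(cfg), model$fingerprint))
    stop(sprintf("feature config mismatch: model %s vs requested %s",
                 model$fingerprint, config_fingerprint(cfg)))
  if (!length(ds$loci)) stop("dataset has no loci (was the matrix filtered empty?)")
  if (length(populations(ds)) < 2L) stop("need >= 2 populations to classify")
  tb <- feature_table(ds, cfg)
  pred <- predict_pairs(model, as.matrix(tb[, model$feature_names]))
  out <- data.frame(popA = tb$popA, popB = tb$popB,
                    label = pred$label, p_same = pred$p_same)
  attr(out, "provenance") <- model$provenance
  class(out) <- c("pair_classification", class(out))
  out
}

# log-probability matrices from a pair table, pops in sorted order
pair_logp <- function(cls, clip = 1e-6) {
  pops <- sort(unique(c(cls$popA, cls$popB)))
  n <- length(pops)
  want <- utils::combn(pops, 2L)
  have <- paste(pmin(cls$popA, cls$popB), pmax(cls$popA, cls$popB))
  missing <- setdiff(paste(want[1L, ], want[2L, ]), have)
  if (length(missing))
    stop("incomplete pair cover; missing pair(s): ",
         paste(missing, collapse = ", "))
  p <- pmin(pmax(cls$p_same, clip), 1 - clip)
  lp <- ld <- matrix(0, n, n, dimnames = list(pops, pops))
  ia <- match(cls$popA, pops); ib <- match(cls$popB, pops)
  lp[cbind(ia, ib)] <- lp[cbind(ib, ia)] <- log(p)
  ld[cbind(ia, ib)] <- ld[cbind(ib, ia)] <- log(1 - p)
  list(pops = pops, lp = lp, ld = ld)
}

partition_score <- function(assign, lp, ld) {
  n <- length(assign)
  s <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    s <- s + if (assign[i] == assign[j]) lp[i, j] else ld[i, j]
  s
}

# exhaustive search over set partitions in restricted-growth order;
# ties resolved toward fewer blocks, then first (lexicographic) encountered
exact_partition <- function(lp, ld) {
  n <- nrow(lp)
  best <- list(score = -Inf, assign = NULL, k = Inf)
  assign <- integer(n)
  tol <- 1e-9
  recurse <- function(i, kmax, score) {
    if (i > n) {
      if (score > best$score + tol ||
          (abs(score - best$score) <= tol && kmax < best$k)) {
        best <<- list(score = score, assign = assign[seq_len(n)], k = kmax)
      }
      return(invisible())
    }
    for (b in seq_len(kmax + 1L)) {
      delta <- 0
      for (j in seq_len(i - 1L))
        delta <- delta + if (assign[j] == b) lp[j, i] else ld[j, i]
      assign[i] <<- b
      recurse(i + 1L, max(kmax, b), score + delta)
    }
  }
  recurse(1L, 0L, 0)
  best
}

# greedy agglomeration + one relocation sweep for large population sets
greedy_partition <- function(lp, ld) {
  n <- nrow(lp)
  assign <- seq_len(n)
  score <- partition_score(assign, lp, ld)
  repeat {
    blocks <- unique(assign)
    best_gain <- 0; best_merge <- NULL
    for (a in seq_along(blocks)) for (b in seq_along(blocks)) {
      if (a >= b) next
      ia <- which(assign == blocks[a]); ib <- which(assign == blocks[b])
      gain <- sum(lp[ia, ib] - ld[ia, ib])
      if (gain > best_gain + 1e-12) { best_gain <- gain; best_merge <- c(a, b) }
    }
    if (is.null(best_merge)) break
    assign[assign == blocks[best_merge[2L]]] <- blocks[best_merge[1L]]
    score <- score + best_gain
  }
  # single relocation pass
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    cand <- c(unique(assign[others]), max(assign) + 1L)
    gains <- vapply(cand, function(b) {
      sum(ifelse(assign[others] == b, lp[i, others], ld[i, others]))
    }, numeric(1))
    cur <- sum(ifelse(assign[others] == assign[i], lp[i, others], ld[i, others]))
    best <- cand[which.max(gains)]
    if (max(gains) > cur + 1e-12) {
      assign[i] <- best
      score <- score + max(gains) - cur
    }
  }
  k <- length(unique(assign))
  list(score = score, assign = assign, k = k)
}

#' Aggregate pairwise classifications into a species partition
#'
#' Finds the partition of populations into species maximizing the total
#' log-probability of the implied pair labels: `log(p_same)` for pairs in
#' the same block, `log(1 - p_same)` for pairs in different blocks
#' (probabilities clipped away from 0/1 before taking logs). The search is
#' exhaustive over set partitions up to `exact_limit` populations, else
#' greedy agglomerative merging followed by a single relocation sweep.
#' Score ties are broken toward fewer species, then lexicographically. This
#' objective degrades gracefully under conflicting (non-transitive)
#' pairwise calls.
#'
#' @param cls a `pair_classification` table covering all pairs of the
#'   population set.
#' @param exact_limit maximum population count for exhaustive search.
#' @param clip probability clipping bound.
#' @return an object of class `species_partition`: a list with `blocks`
#'   (named integer vector, population -> species index, indices contiguous
#'   from 1 in order of first appearance over sorted populations), `k`, and
#'   `score`.
#' @export
aggregate_partition <- function(cls, exact_limit = 10L, clip = 1e-6) {
  m <- pair_logp(cls, clip)
  n <- length(m$pops)
  res <- if (n <= exact_limit) exact_partition(m$lp, m$ld)
         else greedy_partition(m$lp, m$ld)
  # renumber blocks contiguously in order of first appearance
  blocks <- match(res$assign, unique(res$assign))
  structure(list(blocks = stats::setNames(blocks, m$pops),
                 k = length(unique(blocks)), score = res$score),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("species_partition: K = %d (score %.4f)\n", x$k, x$score))
  for (b in seq_len(x$k))
    cat(sprintf("  species %d: %s\n", b,
                paste(names(x$blocks)[x$blocks == b], collapse = ", ")))
  invisible(x)
}

#' Delimit species in a focal dataset
#'
#' Convenience composition of [classify_pairs()] and
#' [aggregate_partition()]; returns both the species partition and the
#' per-pair evidence behind it.
#'
#' @inheritParams classify_pairs
#' @param exact_limit,clip passed to [aggregate_partition()].
#' @param quiet suppress the per-block membership message.
#' @return list with elements `partition` (a `species_partition`) and
#'   `pairs` (a `pair_classification`).
#' @export
delimit <- function(model, ds, cfg = feature_config(), exact_limit = 10L,
                    clip = 1e-6, quiet = FALSE) {
  cls <- classify_pairs(model, ds, cfg)
  part <- aggregate_partition(cls, exact_limit, clip)
  if (!quiet) {
    message(sprintf("delimited K = %d species from %d populations (%s training)",
                    part$k, length(part$blocks),
                    attr(cls, "provenance") %||% "unknown"))
    for (b in seq_len(part$k))
      message(sprintf("  species %d: %s", b,
                      paste(names(part$blocks)[part$blocks == b], collapse = ", ")))
  }
  list(partition = part, pairs = cls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a species partition to JSON and TSV
#' @param part a `species_partition`.
#' @param path_prefix output files `<prefix>.json` and `<prefix>.tsv`.
#' @return invisibly, the two paths.
#' @export
write_partition <- function(part, path_prefix) {
  stopifnot(inherits(part, "species_partition"))
  jpath <- paste0(path_prefix, ".json")
  tpath <- paste0(path_prefix, ".tsv")
  by_block <- split(names(part$blocks), part$blocks)
  jsonlite::write_json(list(k = part$k, score = part$score,
                            species = by_block),
                       jpath, auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(population = names(part$blocks),
                                species = unname(part$blocks)),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jpath, tpath))
}
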