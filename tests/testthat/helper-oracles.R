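# Independent brute-force oracles: explicit character-level loops, kept
# deliberately naive and separate from the package's vectorized code paths.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_res <- function(x) ifelse(x %in% ORACLE_BASES, x, NA_character_)

# pooled (mismatches, sites) over an explicit list of sequence pairs
oracle_accumulate <- function(pairs) {
  d <- s <- 0
  for (pr in pairs) {
    x <- oracle_res(pr[[1]]); y <- oracle_res(pr[[2]])
    for (col in seq_along(x)) {
      if (!is.na(x[col]) && !is.na(y[col])) {
        s <- s + 1
        if (x[col] != y[col]) d <- d + 1
      }
    }
  }
  c(d = d, s = s)
}

oracle_locus_rows <- function(ds, pop) {
  ids <- ds$sample_map$sample[ds$sample_map$population == pop]
  lapply(ds$loci, function(sq) sq[intersect(rownames(sq), ids), , drop = FALSE])
}

oracle_shared <- function(ds, popA, popB) {
  la <- oracle_locus_rows(ds, popA); lb <- oracle_locus_rows(ds, popB)
  keep <- vapply(seq_along(la), function(i) nrow(la[[i]]) > 0 && nrow(lb[[i]]) > 0,
                 logical(1))
  list(a = la[keep], b = lb[keep])
}

oracle_diversity <- function(ds, popA, popB) {
  sh <- oracle_shared(ds, popA, popB)
  within_pairs <- function(ms) {
    out <- list()
    for (m in ms) {
      n <- nrow(m)
      if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
        out[[length(out) + 1]] <- list(m[i, ], m[j, ])
    }
    out
  }
  cross_pairs <- function(ma, mb) {
    out <- list()
    for (k in seq_along(ma)) for (i in seq_len(nrow(ma[[k]])))
      for (j in seq_len(nrow(mb[[k]])))
        out[[length(out) + 1]] <- list(ma[[k]][i, ], mb[[k]][j, ])
    out
  }
  rat <- function(v) if (v[["s"]] > 0) v[["d"]] / v[["s"]] else 0
  c(pi_A = rat(oracle_accumulate(within_pairs(sh$a))),
    pi_B = rat(oracle_accumulate(within_pairs(sh$b))),
    d_xy = rat(oracle_accumulate(cross_pairs(sh$a, sh$b))))
}

oracle_private <- function(ds, popA, popB) {
  sh <- oracle_shared(ds, popA, popB)
  seg <- priv <- 0
  for (k in seq_along(sh$a)) {
    for (col in seq_len(ncol(sh$a[[k]]))) {
      ra <- oracle_res(sh$a[[k]][, col]); ra <- ra[!is.na(ra)]
      rb <- oracle_res(sh$b[[k]][, col]); rb <- rb[!is.na(rb)]
      pooled <- c(ra, rb)
      if (length(pooled) >= 2 && length(unique(pooled)) >= 2) {
        seg <- seg + 1
        for (al in unique(pooled)) {
          inA <- al %in% ra; inB <- al %in% rb
          if (xor(inA, inB)) { priv <- priv + 1; break }
        }
      }
    }
  }
  if (seg == 0) 0 else priv / seg
}

oracle_sfs <- function(ds, popA, popB, k_bins) {
  sh <- oracle_shared(ds, popA, popB)
  counts <- numeric(k_bins)
  for (k in seq_along(sh$a)) {
    for (col in seq_len(ncol(sh$a[[k]]))) {
      pooled <- oracle_res(c(sh$a[[k]][, col], sh$b[[k]][, col]))
      pooled <- pooled[!is.na(pooled)]
      tab <- sort(table(factor(pooled, levels = ORACLE_BASES)), decreasing = TRUE)
      # table sorts ties by factor (alphabetic) order, matching the tie rule
      if (length(pooled) >= 2 && sum(tab > 0) >= 2) {
        c1 <- as.integer(tab[1]); c2 <- as.integer(tab[2])
        bin <- 1
        while (2 * k_bins * c2 > bin * (c1 + c2)) bin <- bin + 1
        counts[bin] <- counts[bin] + 1
      }
    }
  }
  if (sum(counts) == 0) numeric(k_bins) else counts / sum(counts)
}

oracle_tract <- function(ds, popA, popB) {
  sh <- oracle_shared(ds, popA, popB)
  per_locus <- numeric(length(sh$a))
  for (k in seq_along(sh$a)) {
    best <- 0
    for (i in seq_len(nrow(sh$a[[k]]))) for (j in seq_len(nrow(sh$b[[k]])))  {
      x <- oracle_res(sh$a[[k]][i, ]); y <- oracle_res(sh$b[[k]][j, ])
      run <- 0
      for (col in seq_along(x)) {
        if (!is.na(x[col]) && !is.na(y[col]) && x[col] == y[col]) {
          run <- run + 1
          if (run > best) best <- run
        } else run <- 0
      }
    }
    per_locus[k] <- best / ncol(sh$a[[k]])
  }
  mean(per_locus)
}

# exhaustive set-partition optimum by full per-partition rescoring
oracle_partition <- function(cls, clip = 1e-6) {
  pops <- sort(unique(c(cls$popA, cls$popB)))
  n <- length(pops)
  p <- pmin(pmax(cls$p_same, clip), 1 - clip)
  lookup <- new.env()
  for (r in seq_len(nrow(cls)))
    assign(paste(min(cls$popA[r], cls$popB[r]), max(cls$popA[r], cls$popB[r])),
           p[r], envir = lookup)
  all_assignments <- list()
  grow <- function(vec) {
    if (length(vec) == n) { all_assignments[[length(all_assignments) + 1]] <<- vec; return() }
    for (b in seq_len(max(vec) + 1)) grow(c(vec, b))
  }
  grow(1L)
  score_of <- function(vec) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pij <- get(paste(pops[i], pops[j]), envir = lookup)
      s <- s + if (vec[i] == vec[j]) log(pij) else log(1 - pij)
    }
    s
  }
  best <- NULL; best_score <- -Inf; best_k <- Inf
  for (vec in all_assignments) {
    sc <- score_of(vec); k <- max(vec)
    if (sc > best_score + 1e-9 ||
        (abs(sc - best_score) <= 1e-9 && k < best_k)) {
      best <- vec; best_score <- sc; best_k <- k
    }
  }
  list(assign = stats::setNames(best, pops), score = best_score, k = best_k)
}
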