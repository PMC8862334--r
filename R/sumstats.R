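#' Feature configuration
#'
#' Controls how population-pair summary statistics are computed. `k_bins`
#' sets the number of folded site-frequency-spectrum bins; the default of 5
#' gives a 9-dimensional feature vector. Missing data (`N`, `?`, `-`) are
#' always handled by pairwise deletion, and a minor-allele frequency that
#' falls exactly on a bin boundary is assigned to the lower bin (bins are
#' lower-open, upper-closed).
#'
#' @param k_bins number of folded-SFS bins (>= 2).
#' @param gap_policy missing-data policy; only `"pairwise-delete"` is defined.
#' @param sfs_tie bin-boundary rule; only `"lower-bin"` is defined.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(k_bins = 5L, gap_policy = "pairwise-delete",
                           sfs_tie = "lower-bin") {
  k_bins <- as.integer(k_bins)
  stopifnot(length(k_bins) == 1L, k_bins >= 2L)
  gap_policy <- match.arg(gap_policy, "pairwise-delete")
  sfs_tie <- match.arg(sfs_tie, "lower-bin")
  structure(list(k_bins = k_bins, gap_policy = gap_policy, sfs_tie = sfs_tie),
            class = "feature_config")
}

#' Fingerprint of a feature configuration
#'
#' A short string identifying the configuration; stored inside trained models
#' and checked at classification time so a model is never applied to features
#' computed under different settings.
#' @param cfg a [feature_config].
#' @return character scalar.
#' @export
config_fingerprint <- function(cfg) {
  stopifnot(inherits(cfg, "feature_config"))
  sprintf("k%d|%s|%s", cfg$k_bins, cfg$gap_policy, cfg$sfs_tie)
}

#' Names of the features, in the package's fixed order
#' @param cfg a [feature_config].
#' @return character vector of length `4 + k_bins`.
#' @export
feature_names <- function(cfg) {
  c("private", paste0("sfs", seq_len(cfg$k_bins)), "ratio", "fst", "tract")
}

BASES <- c("A", "C", "G", "T")

# Integer-encode an alignment: A=1 C=2 G=3 T=4, anything else NA (missing).
encode_alignment <- function(sq) {
  m <- match(sq, BASES)
  dim(m) <- dim(sq)
  rownames(m) <- rownames(sq)
  m
}

# Loci at which both populations have >= 1 sequence; returns list of
# list(a = integer matrix popA rows, b = integer matrix popB rows).
shared_locus_pairs <- function(ds, popA, popB) {
  stopifnot(inherits(ds, "multilocus_dataset"))
  if (identical(popA, popB)) stop("popA and popB must differ")
  if (!length(ds$loci)) stop("dataset has no loci")
  sa <- pop_samples(ds, popA)
  sb <- pop_samples(ds, popB)
  if (!length(sa)) stop("unknown or empty population: ", popA)
  if (!length(sb)) stop("unknown or empty population: ", popB)
  out <- list()
  for (id in names(ds$loci)) {
    sq <- ds$loci[[id]]
    ra <- intersect(rownames(sq), sa)
    rb <- intersect(rownames(sq), sb)
    if (length(ra) && length(rb)) {
      e <- encode_alignment(sq)
      out[[id]] <- list(a = e[ra, , drop = FALSE], b = e[rb, , drop = FALSE])
    }
  }
  if (!length(out)) stop("no locus shared by populations ", popA, " and ", popB)
  out
}

# Mismatches and comparable sites for one pair of encoded sequences
# (pairwise deletion: columns where either residue is missing are dropped).
pair_diff <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  c(diff = sum(x[ok] != y[ok]), sites = sum(ok))
}

# Accumulate (mismatches, sites) over all pairs drawn from rows of m1 x m2;
# m2 = NULL means all unordered pairs within m1.
accumulate_pairs <- function(m1, m2 = NULL) {
  tot <- c(diff = 0, sites = 0)
  if (is.null(m2)) {
    n <- nrow(m1)
    if (n < 2L) return(tot)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      tot <- tot + pair_diff(m1[i, ], m1[j, ])
  } else {
    for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2)))
      tot <- tot + pair_diff(m1[i, ], m2[j, ])
  }
  tot
}

#' Within- and between-population nucleotide diversity
#'
#' Per-site mean pairwise differences pooled over all sequence pairs and all
#' shared loci (ratio of summed mismatches to summed comparable sites, with
#' pairwise deletion of `N`/`-` columns): `pi_A`, `pi_B` within each
#' population and `d_xy` across them. A population represented by a single
#' haplotype at every locus has no within-population pair; its pi is 0.
#'
#' @param ds a [multilocus_dataset].
#' @param popA,popB population ids (must differ).
#' @return named numeric vector `c(pi_A, pi_B, d_xy)`.
#' @export
diversity_stats <- function(ds, popA, popB) {
  loci <- shared_locus_pairs(ds, popA, popB)
  wa <- wb <- bt <- c(diff = 0, sites = 0)
  for (lp in loci) {
    wa <- wa + accumulate_pairs(lp$a)
    wb <- wb + accumulate_pairs(lp$b)
    bt <- bt + accumulate_pairs(lp$a, lp$b)
  }
  if (bt["sites"] == 0)
    stop("no comparable sites between populations ", popA, " and ", popB)
  ratio0 <- function(v) if (v[["sites"]] > 0) v[["diff"]] / v[["sites"]] else 0
  c(pi_A = ratio0(wa), pi_B = ratio0(wb), d_xy = ratio0(bt))
}

#' Hudson-style FST from diversity components
#'
#' `1 - ((pi_A + pi_B)/2) / d_xy`, the two-deme fixation index comparing
#' mean within-population diversity to between-population divergence.
#' Negative values are not clamped. When `d_xy` is 0 (no between-population
#' variation) the index is defined as 0.
#'
#' @param pi_A,pi_B,d_xy nonnegative per-site diversities.
#' @return numeric FST (<= 1).
#' @export
compute_fst <- function(pi_A, pi_B, d_xy) {
  if (any(c(pi_A, pi_B, d_xy) < 0)) stop("diversities must be nonnegative")
  if (d_xy == 0) return(0)
  1 - ((pi_A + pi_B) / 2) / d_xy
}

#' Within/between pairwise-difference ratio
#'
#' `((pi_A + pi_B)/2) / d_xy`; near 1 under panmixia, near 0 for deeply
#' diverged pairs. When `d_xy` is 0 the ratio is 1 if there is no diversity
#' at all, otherwise it is capped at the sentinel value 10 so the feature
#' stays bounded for classifier scaling.
#'
#' @inheritParams compute_fst
#' @return nonnegative numeric.
#' @export
pairwise_difference_ratio <- function(pi_A, pi_B, d_xy) {
  if (any(c(pi_A, pi_B, d_xy) < 0)) stop("diversities must be nonnegative")
  if (d_xy == 0) return(if (pi_A + pi_B == 0) 1 else 10)
  ((pi_A + pi_B) / 2) / d_xy
}

# Per-column allele counts (4 x L) for an encoded matrix.
base_counts <- function(e) {
  L <- ncol(e)
  out <- matrix(0L, 4L, L)
  for (b in 1:4) out[b, ] <- colSums(e == b, na.rm = TRUE)
  out
}

#' Fraction of segregating sites carrying a private allele
#'
#' Over all segregating sites in the pooled pair (columns with >= 2
#' non-missing residues and >= 2 alleles, gaps/`N` treated as missing,
#' pooled over shared loci), the fraction of sites at which at least one
#' allele is observed in exactly one of the two populations.
#'
#' @inheritParams diversity_stats
#' @return fraction in `[0, 1]`; 0 when there is no segregating site.
#' @export
private_positions <- function(ds, popA, popB) {
  loci <- shared_locus_pairs(ds, popA, popB)
  seg <- priv <- 0L
  for (lp in loci) {
    ca <- base_counts(lp$a); cb <- base_counts(lp$b)
    cp <- ca + cb
    nm <- colSums(cp)                      # non-missing pooled residues
    nal <- colSums(cp > 0L)                # distinct alleles
    is_seg <- nm >= 2L & nal >= 2L
    if (!any(is_seg)) next
    pa <- ca > 0L; pb <- cb > 0L
    has_priv <- colSums((pa & !pb) | (pb & !pa)) > 0L
    seg <- seg + sum(is_seg)
    priv <- priv + sum(has_priv & is_seg)
  }
  if (seg == 0L) return(0)
  priv / seg
}

#' Binned folded site-frequency spectrum of the pooled pair
#'
#' For every pooled segregating site the minor-allele frequency
#' `f in (0, 0.5]` is computed and binned into `k_bins` equal lower-open,
#' upper-closed intervals of `(0, 0.5]`; `f = 0.5` falls in the top bin.
#' Sites with more than two alleles are reduced to their two most frequent
#' alleles (count ties broken alphabetically, which never changes `f`).
#' Counts are normalized by the number of segregating sites.
#'
#' @inheritParams diversity_stats
#' @param k_bins number of bins (>= 2).
#' @return numeric vector of `k_bins` fractions summing to 1, or all zero
#'   when no site segregates.
#' @export
folded_sfs <- function(ds, popA, popB, k_bins = 5L) {
  k_bins <- as.integer(k_bins)
  stopifnot(k_bins >= 2L)
  loci <- shared_locus_pairs(ds, popA, popB)
  counts <- integer(k_bins)
  for (lp in loci) {
    cp <- base_counts(lp$a) + base_counts(lp$b)
    # top-2 allele counts per column: max, and max of pairwise minima
    m1 <- pmax(cp[1, ], cp[2, ], cp[3, ], cp[4, ])
    m2 <- pmax(pmin(cp[1, ], cp[2, ]), pmin(cp[1, ], cp[3, ]),
               pmin(cp[1, ], cp[4, ]), pmin(cp[2, ], cp[3, ]),
               pmin(cp[2, ], cp[4, ]), pmin(cp[3, ], cp[4, ]))
    seg <- m2 > 0L                         # >= 2 alleles after top-2 reduction
    if (!any(seg)) next
    num <- m2[seg]; den <- m1[seg] + m2[seg]
    # bin = ceiling(f / (0.5/k)) with f = num/den, in exact integer arithmetic
    bin <- (2L * k_bins * num + den - 1L) %/% den
    counts <- counts + tabulate(bin, nbins = k_bins)
  }
  if (sum(counts) == 0L) return(numeric(k_bins))
  counts / sum(counts)
}

#' Longest shared identical tract between populations
#'
#' Per shared locus, over all cross-population sequence pairs, the longest
#' run of consecutive columns at which the two sequences carry the same
#' unambiguous residue (neither `N` nor `-`), divided by locus length; the
#' statistic is the mean across loci of these per-locus maxima. Long shared
#' tracts indicate recent common ancestry or gene flow.
#'
#' @inheritParams diversity_stats
#' @return fraction in `[0, 1]`.
#' @export
longest_shared_tract <- function(ds, popA, popB) {
  loci <- shared_locus_pairs(ds, popA, popB)
  per_locus <- vapply(loci, function(lp) {
    L <- ncol(lp$a)
    best <- 0L
    for (i in seq_len(nrow(lp$a))) for (j in seq_len(nrow(lp$b))) {
      eq <- lp$a[i, ] == lp$b[j, ]
      eq[is.na(eq)] <- FALSE
      r <- rle(eq)
      run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      if (run > best) best <- run
    }
    best / L
  }, numeric(1))
  mean(per_locus)
}

#' Assemble the feature vector for one population pair
#'
#' Computes the five classifier features in the package's fixed order:
#' private-allele fraction, the `k_bins` folded-SFS fractions, the
#' within/between pairwise-difference ratio, Hudson's FST, and the longest
#' shared tract. All features are symmetric in the two populations.
#'
#' @inheritParams diversity_stats
#' @param cfg a [feature_config].
#' @return named numeric vector of length `4 + k_bins`.
#' @export
compute_feature_vector <- function(ds, popA, popB, cfg = feature_config()) {
  stopifnot(inherits(cfg, "feature_config"))
  div <- diversity_stats(ds, popA, popB)
  v <- c(private_positions(ds, popA, popB),
         folded_sfs(ds, popA, popB, cfg$k_bins),
         pairwise_difference_ratio(div[["pi_A"]], div[["pi_B"]], div[["d_xy"]]),
         compute_fst(div[["pi_A"]], div[["pi_B"]], div[["d_xy"]]),
         longest_shared_tract(ds, popA, popB))
  stats::setNames(v, feature_names(cfg))
}

#' Feature table for all population pairs of a dataset
#'
#' @param ds a [multilocus_dataset] (complete-matrix filtered).
#' @param cfg a [feature_config].
#' @return data frame with `popA < popB` (lexicographic) and one column per
#'   feature.
#' @export
feature_table <- function(ds, cfg = feature_config()) {
  pops <- populations(ds)
  if (length(pops) < 2L) stop("need at least 2 populations")
  prs <- utils::combn(pops, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(i)
    compute_feature_vector(ds, prs[1L, i], prs[2L, i], cfg))
  out <- data.frame(popA = prs[1L, ], popB = prs[2L, ],
                    do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- NULL
  out
}
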