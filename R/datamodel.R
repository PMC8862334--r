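#' Construct a multilocus dataset
#'
#' A `multilocus_dataset` bundles per-locus alignments with a sample map.
#' Each locus is a character matrix of aligned DNA residues (rows = samples,
#' named by sample id; columns = alignment positions) over the alphabet
#' `A C G T N -`; sequences are stored upper-case, with `?` normalized to `N`.
#' The sample map assigns every sample to a predefined population and a
#' geographic locality, and optionally to a known species (required for
#' "custom" reference training data).
#'
#' @param loci named list of character matrices, one per locus; names are
#'   locus ids. Row names are sample ids; all rows of a locus have equal
#'   length by construction.
#' @param sample_map data frame with columns `sample`, `population`,
#'   `locality`, and optionally `species` (all character).
#' @return an object of class `multilocus_dataset`.
#' @export
multilocus_dataset <- function(loci, sample_map) {
  stopifnot(is.list(loci), is.data.frame(sample_map))
  if (is.null(names(loci)) || anyDuplicated(names(loci)))
    stop("loci must be a named list with unique locus ids")
  loci <- lapply(loci, normalize_alignment)
  sample_map <- validate_sample_map(sample_map)
  for (id in names(loci)) {
    sq <- loci[[id]]
    if (anyDuplicated(rownames(sq)))
      stop(sprintf("duplicate sample ids within locus '%s'", id))
    missing <- setdiff(rownames(sq), sample_map$sample)
    if (length(missing))
      stop(sprintf("sample(s) %s present in locus '%s' but absent from sample map",
                   paste(missing, collapse = ", "), id))
  }
  structure(list(loci = loci, sample_map = sample_map),
            class = "multilocus_dataset")
}

# Upper-case, '?' -> 'N', reject ragged or empty alignments.
normalize_alignment <- function(sq) {
  if (!is.matrix(sq) || !is.character(sq))
    stop("each locus must be a character matrix of single residues")
  if (ncol(sq) < 1L || nrow(sq) < 1L) stop("empty alignment")
  if (is.null(rownames(sq))) stop("alignment rows must be named by sample id")
  sq <- toupper(sq)
  sq[sq == "?"] <- "N"
  sq
}

validate_sample_map <- function(sm) {
  need <- c("sample", "population", "locality")
  if (!all(need %in% names(sm)))
    stop("sample map needs columns sample, population, locality (species optional)")
  keep <- intersect(c(need, "species"), names(sm))
  sm <- sm[, keep, drop = FALSE]
  sm[] <- lapply(sm, as.character)
  if (anyDuplicated(sm$sample))
    stop("duplicate sample ids in sample map")
  if ("species" %in% names(sm)) {
    if (anyNA(sm$species) || any(sm$species == ""))
      stop("species column must be present for all samples or absent entirely")
    # each population must map to a single species
    sp <- tapply(sm$species, sm$population, function(x) length(unique(x)))
    if (any(sp > 1L))
      stop("population(s) mapped to more than one species: ",
           paste(names(sp)[sp > 1L], collapse = ", "))
  }
  rownames(sm) <- NULL
  sm
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  np <- length(unique(x$sample_map$population))
  cat(sprintf("multilocus_dataset: %d loci, %d samples, %d populations%s\n",
              length(x$loci), nrow(x$sample_map), np,
              if ("species" %in% names(x$sample_map))
                sprintf(", %d labeled species", length(unique(x$sample_map$species)))
              else ""))
  invisible(x)
}

#' Population ids of a dataset
#' @param ds a `multilocus_dataset`.
#' @return character vector of population ids, sorted.
#' @export
populations <- function(ds) sort(unique(ds$sample_map$population))

# samples of one population
pop_samples <- function(ds, pop) ds$sample_map$sample[ds$sample_map$population == pop]

#' Keep only loci at which every population is represented
#'
#' Mirrors the complete-matrix requirement of pairwise classification: a locus
#' is retained only when every predefined population contributes at least one
#' sequence to its alignment. Locus order is preserved and retained alignments
#' are returned unaltered. The operation is idempotent.
#'
#' @param ds a `multilocus_dataset`.
#' @return a `multilocus_dataset` with the surviving loci; if no locus
#'   survives, an empty dataset is returned with a warning (downstream
#'   operations reject empty datasets).
#' @export
filter_complete_matrix <- function(ds) {
  stopifnot(inherits(ds, "multilocus_dataset"))
  pops <- populations(ds)
  pop_of <- stats::setNames(ds$sample_map$population, ds$sample_map$sample)
  keep <- vapply(ds$loci, function(sq) {
    present <- unique(pop_of[rownames(sq)])
    all(pops %in% present)
  }, logical(1))
  if (!any(keep))
    warning("no locus has every population represented; empty dataset returned")
  out <- ds
  out$loci <- ds$loci[keep]
  out
}
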