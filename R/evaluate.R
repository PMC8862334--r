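#' Same-locality consistency of pairwise classifications
#'
#' In low-dispersal taxa undergoing nonecological speciation, related
#' congeners are allopatric, so specimens collected at the same locality
#' should be conspecific; the mean calibrated same-species probability over
#' co-located population pairs is therefore a proxy for classifier quality
#' when no ground truth exists. Two populations count as co-located when
#' they share at least one locality id.
#'
#' @param cls a `pair_classification` table.
#' @param sm sample map data frame (or a [multilocus_dataset], whose map is
#'   used) assigning every classified population to localities.
#' @return an object of class `consistency_report`: list with
#'   `mean_p_same_colocated` (NA when no co-located pair exists), `n_pairs`,
#'   `pairs` (contributing rows of `cls`), and `provenance`.
#' @export
same_locality_consistency <- function(cls, sm) {
  if (inherits(sm, "multilocus_dataset")) sm <- sm$sample_map
  stopifnot(is.data.frame(cls), is.data.frame(sm))
  pops <- unique(c(cls$popA, cls$popB))
  known <- unique(sm$population)
  if (!all(pops %in% known))
    stop("population(s) not in sample map: ",
         paste(setdiff(pops, known), collapse = ", "))
  locs <- lapply(stats::setNames(pops, pops), function(p)
    unique(sm$locality[sm$population == p]))
  shared <- mapply(function(a, b) length(intersect(locs[[a]], locs[[b]])) > 0L,
                   cls$popA, cls$popB)
  sub <- cls[shared, , drop = FALSE]
  structure(list(
    mean_p_same_colocated = if (nrow(sub)) mean(sub$p_same) else NA_real_,
    n_pairs = nrow(sub),
    pairs = sub,
    provenance = attr(cls, "provenance") %||% "unknown"),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency_report (%s): %d co-located pair(s), mean p_same = %s\n",
              x$provenance, x$n_pairs,
              if (is.na(x$mean_p_same_colocated)) "n/a"
              else sprintf("%.3f", x$mean_p_same_colocated)))
  invisible(x)
}

#' Compare same-locality consistency between training regimes
#'
#' Contrasts two consistency reports computed from the same dataset and
#' population-pair set (typically general- vs custom-trained models):
#' reports both means, the difference `custom - general` (second minus
#' first), per-pair probability deltas, and the direction of the effect.
#'
#' @param report_general,report_custom `consistency_report` objects from
#'   the same classified pair set.
#' @return list with `mean_general`, `mean_custom`, `delta`, `direction`
#'   (`"custom > general"`, `"general > custom"` or `"equal"`), and
#'   `per_pair` (data frame of per-pair deltas).
#' @export
compare_regimes <- function(report_general, report_custom) {
  stopifnot(inherits(report_general, "consistency_report"),
            inherits(report_custom, "consistency_report"))
  key <- function(r) paste(r$pairs$popA, r$pairs$popB)
  if (!identical(sort(key(report_general)), sort(key(report_custom))))
    stop("reports cover different population-pair sets")
  g <- report_general$pairs[order(key(report_general)), , drop = FALSE]
  c_ <- report_custom$pairs[order(key(report_custom)), , drop = FALSE]
  delta <- report_custom$mean_p_same_colocated - report_general$mean_p_same_colocated
  per_pair <- data.frame(popA = g$popA, popB = g$popB,
                         p_same_general = g$p_same, p_same_custom = c_$p_same,
                         delta = c_$p_same - g$p_same)
  list(mean_general = report_general$mean_p_same_colocated,
       mean_custom = report_custom$mean_p_same_colocated,
       delta = delta,
       direction = if (isTRUE(delta > 0)) "custom > general"
                   else if (isTRUE(delta < 0)) "general > custom" else "equal",
       per_pair = per_pair)
}
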