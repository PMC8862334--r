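#' Learn a per-feature linear scaling to [-1, 1]
#'
#' Maps each feature linearly so that the training minimum maps to -1 and the
#' training maximum to +1 (the convention of LibSVM's svm-scale). A constant
#' feature always maps to 0. The transform is learned on training data only
#' and applied unchanged to test vectors, which may therefore fall outside
#' `[-1, 1]`.
#'
#' @param train numeric matrix (rows = training feature vectors) or data
#'   frame of numeric feature columns.
#' @return an object of class `scaling_transform` holding per-feature
#'   `(min, max)`.
#' @export
fit_scaling <- function(train) {
  m <- as.matrix(train)
  if (!is.numeric(m) || nrow(m) < 1L) stop("need a non-empty numeric training matrix")
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max),
                 names = colnames(m)),
            class = "scaling_transform")
}

#' @rdname fit_scaling
#' @param t a `scaling_transform`.
#' @param v numeric feature vector or matrix with matching columns.
#' @return scaled vector/matrix of the same shape.
#' @export
apply_scaling <- function(t, v) {
  stopifnot(inherits(t, "scaling_transform"))
  one <- is.null(dim(v))
  m <- if (one) matrix(v, nrow = 1L, dimnames = list(NULL, names(v))) else as.matrix(v)
  if (ncol(m) != length(t$min)) stop("feature count mismatch with scaling transform")
  rng <- t$max - t$min
  out <- m
  for (j in seq_along(rng)) {
    out[, j] <- if (rng[j] == 0) 0 else 2 * (m[, j] - t$min[j]) / rng[j] - 1
  }
  if (one) stats::setNames(drop(out), names(v)) else out
}

#' Serialize / deserialize a scaling transform as JSON
#' @param t a `scaling_transform`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_scaling_json()` returns the transform.
#' @export
write_scaling_json <- function(t, path) {
  stopifnot(inherits(t, "scaling_transform"))
  jsonlite::write_json(
    list(feature = if (is.null(t$names)) paste0("f", seq_along(t$min)) else t$names,
         min = unname(t$min), max = unname(t$max)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_scaling_json
#' @export
read_scaling_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = stats::setNames(as.numeric(x$min), x$feature),
                 max = stats::setNames(as.numeric(x$max), x$feature),
                 names = x$feature),
            class = "scaling_transform")
}
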