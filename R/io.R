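#' Read per-locus alignments and a sample map
#'
#' Reads a directory (or a single file) of per-locus multiple sequence
#' alignments, one file per locus, together with a tab-separated sample map,
#' into a [multilocus_dataset]. Locus ids are taken from file name stems.
#' Sequence case is normalized to upper and `?` to `N`. A sample listed in
#' the map but absent from every locus is accepted (samples may lack data at
#' some loci); a sequence whose id is missing from the map is an error.
#'
#' @param path directory containing one alignment file per locus, or a single
#'   alignment file (one locus).
#' @param format `"fasta"` or `"phylip"` (relaxed sequential PHYLIP).
#' @param sample_map_path TSV file with header columns
#'   `sample`, `population`, `locality` and optionally `species`.
#' @return a [multilocus_dataset].
#' @examples
#' dir <- system.file("extdata", "toy_fasta", package = "specdelim")
#' ds <- read_locus_alignments(dir, "fasta",
#'                             file.path(dir, "sample_map.tsv"))
#' @export
read_locus_alignments <- function(path, format = c("fasta", "phylip"),
                                  sample_map_path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  sm <- read_sample_map(sample_map_path)
  ext <- c(fasta = "\\.(fa|fas|fasta)$", phylip = "\\.(phy|phylip)$")[format]
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = ext, full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no ", format, " alignment files found under ", path)
  } else files <- path
  loci <- lapply(files, read_one_alignment, format = format)
  names(loci) <- tools::file_path_sans_ext(basename(files))
  multilocus_dataset(loci, sm)
}

read_one_alignment <- function(file, format) {
  locus <- tools::file_path_sans_ext(basename(file))
  sq <- tryCatch(
    if (format == "fasta") ape::read.dna(file, format = "fasta", as.character = TRUE,
                                         as.matrix = FALSE)
    else ape::read.dna(file, format = "sequential", as.character = TRUE,
                       as.matrix = FALSE),
    error = function(e) stop(sprintf("could not parse locus '%s': %s",
                                     locus, conditionMessage(e)), call. = FALSE))
  if (is.matrix(sq)) return(toupper(sq))
  lens <- lengths(sq)
  if (length(unique(lens)) > 1L)
    stop(sprintf("alignment error in locus '%s': unequal sequence lengths (%s)",
                 locus, paste(sort(unique(lens)), collapse = ", ")))
  m <- do.call(rbind, sq)
  rownames(m) <- names(sq)
  toupper(m)
}

#' Read a sample map TSV
#'
#' @param path TSV with header `sample  population  locality  [species]`.
#' @return data frame of character columns.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("sample map not found: ", path)
  sm <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (ncol(sm) < 3L || ncol(sm) > 4L)
    stop("sample map must have 3-4 tab-separated columns")
  validate_sample_map(sm)
}

#' Write a dataset as one FASTA file per locus plus a sample map TSV
#'
#' The on-disk layout round-trips through [read_locus_alignments()]:
#' `<dir>/<locus_id>.fasta` for every locus and `<dir>/sample_map.tsv`.
#'
#' @param ds a [multilocus_dataset].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus_alignments <- function(ds, dir) {
  stopifnot(inherits(ds, "multilocus_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(ds$loci)) {
    bin <- ape::as.DNAbin(tolower(ds$loci[[id]]))
    ape::write.dna(bin, file.path(dir, paste0(id, ".fasta")),
                   format = "fasta", colsep = "")
  }
  utils::write.table(ds$sample_map, file.path(dir, "sample_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write / read a population-pair feature table
#'
#' The table has one row per population pair: columns `popA`, `popB`, then
#' one column per feature in the package's fixed order
#' (`private`, `sfs1..sfsK`, `ratio`, `fst`, `tract`), and optionally a
#' `label` column. Values round-trip losslessly at 12 significant digits.
#'
#' @param rows data frame with `popA`, `popB` and numeric feature columns
#'   (as returned by feature assembly), or a list of rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("rows must be a data frame")
  if (nrow(rows) == 0L) stop("empty feature table")
  need <- c("popA", "popB")
  if (!all(need %in% names(rows))) stop("feature table needs popA and popB columns")
  num <- setdiff(names(rows), c("popA", "popB", "label"))
  out <- rows
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  tb$popA <- as.character(tb$popA)
  tb$popB <- as.character(tb$popB)
  tb
}
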