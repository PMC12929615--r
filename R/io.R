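## Formats: radiograph-benchmark-style label CSV (one row per image, one 0/1
## column per label), binary masks as 0/255 grayscale PNG and as run-length-encoded
## JSON. The RLE dialect is bit-exact: {"size": [S, S], "counts": [...]}
## where counts are run lengths over the column-major flattened mask,
## alternating zero-run / one-run and always starting with a zero-run
## (possibly of length 0).

#' Read a label table
#'
#' CSV with a `path` column followed by one strictly binary column per
#' label. Missing values and non-binary entries are rejected with the
#' offending cell named; the consumer works on already-binarized labels.
#'
#' @param path CSV file path.
#' @param labels optional expected label names; any other label column is
#'   rejected.
#' @return data.frame with `path` plus integer 0/1 label columns.
#' @export
readLabelTable <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
    colClasses = "character")
  if (!"path" %in% names(tab))
    stop("label table must have a 'path' column")
  labCols <- setdiff(names(tab), "path")
  if (length(labCols) == 0L) stop("label table has no label columns")
  if (!is.null(labels)) {
    extra <- setdiff(labCols, labels)
    if (length(extra) > 0L)
      stop("unknown label column(s): ", paste(extra, collapse = ", "))
  }
  for (cc in labCols) {
    v <- tab[[cc]]
    bad <- which(is.na(v) | !v %in% c("0", "1"))
    if (length(bad) > 0L)
      stop("non-binary or missing entry '", v[bad[1]], "' at row ", bad[1],
        ", column '", cc, "'")
    tab[[cc]] <- as.integer(v)
  }
  tab
}

#' Write a label table
#'
#' Canonical form: `path` column first, then 0/1 label columns, no quoting,
#' no row names -- so write/read round-trips byte-wise.
#'
#' @param tab data.frame as returned by [readLabelTable()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLabelTable <- function(tab, path) {
  stopifnot("path" %in% names(tab))
  labCols <- setdiff(names(tab), "path")
  for (cc in labCols) {
    if (any(is.na(tab[[cc]])) || !all(tab[[cc]] %in% c(0L, 1L)))
      stop("column '", cc, "' is not strictly binary")
  }
  utils::write.csv(tab[, c("path", labCols), drop = FALSE], path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run-length encode a binary mask
#'
#' @param mask 0/1 matrix.
#' @return list with `size = c(S, S)` and integer `counts` (column-major
#'   runs, leading zero-run convention).
#' @export
maskToRLE <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly 0/1")
  v <- as.integer(as.vector(mask))
  r <- rle(v)
  counts <- r$lengths
  if (length(v) == 0L) counts <- integer(0)
  else if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

#' Decode a run-length-encoded binary mask
#'
#' @param rle list with `size` and `counts` as produced by [maskToRLE()].
#' @return integer 0/1 matrix.
#' @export
rleToMask <- function(rle) {
  S <- as.integer(rle$size)
  counts <- as.integer(rle$counts)
  total <- prod(S)
  if (sum(counts) != total)
    stop("RLE counts sum to ", sum(counts), ", expected ", total)
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(vals, S[1], S[2])
}

#' Write a binary mask as RLE JSON
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskJSON <- function(mask, path) {
  jsonlite::write_json(maskToRLE(mask), path, auto_unbox = FALSE)
  invisible(path)
}

#' Read a binary mask from RLE JSON
#'
#' @param path input path.
#' @return integer 0/1 matrix.
#' @export
readMaskJSON <- function(path) {
  rleToMask(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly 0/1")
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' Read a binary mask from a 0/255 grayscale PNG
#'
#' @param path input path.
#' @return integer 0/1 matrix.
#' @export
readMaskPNG <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  if (!all(v %in% c(0, 1)))
    stop("mask PNG contains values other than 0 and 255")
  m <- matrix(as.integer(v), nrow(v), ncol(v))
  m
}

#' Read a grayscale image PNG as an intensity matrix
#'
#' @param path input path.
#' @return numeric matrix in `[0, 1]`.
#' @export
readGrayPNG <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  matrix(as.numeric(v), nrow(v), ncol(v))
}

#' Write an intensity matrix as a grayscale PNG
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGrayPNG <- function(img, path) {
  png::writePNG(img, target = path)
  invisible(path)
}
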