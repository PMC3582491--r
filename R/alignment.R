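#' Promoter alignment container
#'
#' Gapped multiple alignment of promoter sequences with a reference row
#' mapped to promoter coordinates. Promoter positions are numbered with the
#' transcription start site at +1 and no position 0, so a region such as
#' -76..-47 spans exactly 30 reference positions.
#'
#' @param seqs named character vector of equal-length gapped sequences over
#'   `A`, `C`, `G`, `T`, `-` (case-insensitive; `N` is treated as a gap).
#' @param reference name of the reference (coordinate-bearing) species.
#' @param first_coord promoter coordinate of the reference row's first
#'   (ungapped) base, e.g. -326.
#' @param taxonomy optional data frame with columns `species`, `group`
#'   and `base_weight` (see [working_weights()]).
#' @param regions named list of 2-vectors of promoter coordinates
#'   (closed intervals), e.g. `list(PRE = c(-76, -47))`.
#' @return A `promoter_alignment` object.
#' @export
promoter_alignment <- function(seqs, reference, first_coord = -326L,
                               taxonomy = NULL,
                               regions = list(PRE = c(-76L, -47L))) {
  stopifnot(!is.null(names(seqs)), reference %in% names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicated species names")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment rows must have equal length")
  mat[mat == "N"] <- "-"
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-"))
  if (length(bad))
    stop("invalid alignment characters: ", paste(bad, collapse = " "))
  ref_row <- mat[reference, ]
  n_ref <- sum(ref_row != "-")
  coords <- promoter_coords(first_coord, n_ref)
  ref_coord <- rep(NA_integer_, ncol(mat))
  ref_coord[ref_row != "-"] <- coords
  if (!is.null(taxonomy)) {
    miss <- setdiff(rownames(mat), taxonomy$species)
    if (length(miss))
      stop("taxonomy is missing species: ", paste(miss, collapse = ", "))
  }
  structure(list(seq = mat, reference = reference,
                 ref_coord = ref_coord, first_coord = first_coord,
                 taxonomy = taxonomy, regions = regions),
            class = "promoter_alignment")
}

#' Promoter coordinate sequence (no position zero)
#'
#' @param from starting promoter coordinate (nonzero).
#' @param n number of positions.
#' @return Integer vector of `n` consecutive promoter coordinates skipping
#'   0.
#' @export
promoter_coords <- function(from, n) {
  if (from == 0) stop("coordinate error: promoter numbering has no 0")
  out <- integer(n)
  x <- as.integer(from)
  for (i in seq_len(n)) {
    out[i] <- x
    x <- x + 1L
    if (x == 0L) x <- 1L
  }
  out
}

#' Map promoter coordinates to alignment columns
#'
#' Bijection between the reference row's ungapped promoter positions and
#' the alignment columns that carry reference residues.
#'
#' @param aln a [promoter_alignment()].
#' @param positions promoter coordinates (nonzero).
#' @return Integer column indices.
#' @seealso [column_coord()] for the inverse.
#' @export
map_coords <- function(aln, positions) {
  stopifnot(inherits(aln, "promoter_alignment"))
  if (any(positions == 0))
    stop("coordinate error: promoter numbering has no position 0")
  idx <- match(positions, aln$ref_coord)
  if (anyNA(idx))
    stop("coordinate error: position(s) ",
         paste(positions[is.na(idx)], collapse = ", "),
         " outside the reference span")
  idx
}

#' Promoter coordinate of an alignment column
#'
#' Inverse of [map_coords()]; columns where the reference row is gapped
#' have no coordinate and return `NA`.
#'
#' @param aln a [promoter_alignment()].
#' @param columns column indices.
#' @export
column_coord <- function(aln, columns) {
  stopifnot(inherits(aln, "promoter_alignment"))
  aln$ref_coord[columns]
}

#' Columns of a named or explicit region
#'
#' Resolves a region (a name from the alignment's region list, or a
#' 2-vector of promoter coordinates) to the alignment columns carrying
#' reference residues within the closed interval.
#'
#' @param aln a [promoter_alignment()].
#' @param region region name or `c(from, to)` promoter coordinates.
#' @export
region_columns <- function(aln, region = "PRE") {
  if (is.character(region) && length(region) == 1) {
    if (!region %in% names(aln$regions))
      stop("unknown region '", region, "'")
    region <- aln$regions[[region]]
  }
  stopifnot(length(region) == 2)
  span <- promoter_span(region[1], region[2])
  map_coords(aln, span)
}

promoter_span <- function(from, to) {
  if (from == 0 || to == 0) stop("coordinate error: no position 0")
  x <- setdiff(seq(from, to), 0L)
  as.integer(x)
}

#' Read a promoter alignment from aligned FASTA
#'
#' @param fasta path to an aligned multi-FASTA file.
#' @param taxonomy optional path to a species metadata TSV with columns
#'   `species`, `group`, `base_weight` (or a data frame).
#' @param reference,first_coord,regions see [promoter_alignment()].
#' @export
read_promoter_alignment <- function(fasta, taxonomy = NULL, reference,
                                    first_coord = -326L,
                                    regions = list(PRE = c(-76L, -47L))) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.character(taxonomy))
    taxonomy <- utils::read.delim(taxonomy, stringsAsFactors = FALSE)
  promoter_alignment(seqs, reference = reference,
                     first_coord = first_coord, taxonomy = taxonomy,
                     regions = regions)
}

#' @export
print.promoter_alignment <- function(x, ...) {
  cat("Promoter alignment: ", nrow(x$seq), " species x ", ncol(x$seq),
      " columns, reference '", x$reference, "' spanning ",
      min(x$ref_coord, na.rm = TRUE), "..",
      max(x$ref_coord, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}
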