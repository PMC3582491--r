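#' Assay replicate table
#'
#' Container for raw replicate measurements of a single assay, grouped by
#' film (autoradiograph or plate batch) and sequence variant. Two
#' measurement scales are supported: `"subtractive"` for densitometric EMSA
#' readings that are standardized within each film, and `"ratio"` for
#' strictly positive reporter (ELISA) readings that are expressed relative
#' to the control.
#'
#' @param records data frame with columns `film`, `variant`, `replicate`,
#'   `signal` and, for ratio assays with a cotransfection control, an
#'   optional `covariate` column (positive, e.g. beta-galactosidase level).
#' @param kind `"subtractive"` or `"ratio"`.
#' @param control label of the control (wildtype) variant.
#' @param assay_id free-text assay label.
#' @return An object of class `assay_table`.
#' @examples
#' rec <- data.frame(film = 1, variant = c("PRE", "A", "B"),
#'                   replicate = 1, signal = c(2, 1, 3))
#' assay_table(rec, kind = "subtractive", control = "PRE")
#' @export
assay_table <- function(records, kind = c("subtractive", "ratio"),
                        control, assay_id = "assay") {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(records))
  need <- c("film", "variant", "replicate", "signal")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  records$film <- as.character(records$film)
  records$variant <- as.character(records$variant)
  if (!all(is.finite(records$signal)))
    stop("all signals must be finite")
  if (!control %in% records$variant)
    stop("control variant '", control, "' not present in records")
  if (kind == "ratio") {
    if (any(records$signal <= 0))
      stop("ratio-scale signals must be strictly positive")
    if (!is.null(records$covariate) && any(records$covariate <= 0))
      stop("covariate values must be strictly positive")
  }
  for (f in unique(records$film)) {
    rf <- records[records$film == f, ]
    if (!control %in% rf$variant)
      stop("design error: control variant '", control,
           "' missing from film '", f, "'")
    if (kind == "subtractive" &&
        (nrow(rf) < 2 || stats::sd(rf$signal) == 0))
      stop("degenerate film '", f, "': needs >= 2 non-identical signals")
  }
  structure(list(assay_id = assay_id, kind = kind, control = control,
                 records = records),
            class = "assay_table")
}

#' Read an assay table from TSV
#'
#' Expects columns `assay_id`, `kind`, `film`, `variant`, `replicate`,
#' `signal` and optionally `covariate`. Multiple assays may share a file;
#' a list of [assay_table()] objects is returned, one per `assay_id`.
#'
#' @param path TSV file path.
#' @param control control variant label.
#' @return Named list of `assay_table` objects.
#' @export
read_assay_tsv <- function(path, control) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(d, d$assay_id), function(x) {
    kind <- unique(x$kind)
    if (length(kind) != 1)
      stop("assay '", x$assay_id[1], "' mixes measurement kinds")
    assay_table(x[setdiff(names(x), c("assay_id", "kind"))],
                kind = kind, control = control,
                assay_id = x$assay_id[1])
  })
}

#' @export
print.assay_table <- function(x, ...) {
  cat("Assay table '", x$assay_id, "' (", x$kind, " scale)\n", sep = "")
  cat("  ", nrow(x$records), " records, ",
      length(unique(x$records$variant)), " variants, ",
      length(unique(x$records$film)), " film(s); control = ",
      x$control, "\n", sep = "")
  invisible(x)
}
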