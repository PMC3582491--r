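#' Transcription-factor site catalog
#'
#' Literal binding-site strings (with optional lowercase 3' context
#' letters) and molecular weights per factor. Matching is case-insensitive
#' and exact.
#'
#' @param df data frame with columns `factor`, `site` and `mw`
#'   (semicolon-separated kDa values, may be empty).
#' @return A `site_catalog` object.
#' @export
site_catalog <- function(df) {
  stopifnot(all(c("factor", "site") %in% names(df)))
  if (any(!nzchar(df$site))) stop("site strings must be non-empty")
  if (is.null(df$mw)) df$mw <- ""
  mw <- lapply(strsplit(as.character(df$mw), ";"), function(x) {
    x <- suppressWarnings(as.numeric(x))
    x[is.finite(x)]
  })
  if (any(unlist(mw) <= 0)) stop("molecular weights must be positive")
  structure(list(factor = as.character(df$factor),
                 site = as.character(df$site), mw = mw),
            class = "site_catalog")
}

#' Scan a sequence against the site catalog
#'
#' Case-insensitive exact substring search on the forward strand over the
#' core sequence plus any 5'/3' context (lowercase context letters in
#' catalog entries are part of the site). All match offsets are reported,
#' 1-based in the concatenated context+core+context string. Reverse-
#' complement scanning is available behind a flag.
#'
#' @param seq core nucleotide sequence (A/C/G/T).
#' @param catalog a [site_catalog()].
#' @param context_5p,context_3p optional flanking context (e.g. plasmid
#'   sequence downstream of an oligomer core).
#' @param revcomp also scan the reverse complement.
#' @return Data frame with `factor`, `site`, `offset`, `strand`.
#' @export
scan_sites <- function(seq, catalog, context_5p = "", context_3p = "",
                       revcomp = FALSE) {
  stopifnot(inherits(catalog, "site_catalog"))
  full <- toupper(paste0(context_5p, seq, context_3p))
  if (grepl("[^ACGT]", full))
    stop("input error: sequence contains non-ACGT characters")
  scan_one <- function(subject, strand) {
    hits <- lapply(seq_along(catalog$site), function(i) {
      pat <- toupper(catalog$site[i])
      pos <- gregexpr(pat, subject, fixed = TRUE)[[1]]
      if (pos[1] == -1) return(NULL)
      data.frame(factor = catalog$factor[i], site = catalog$site[i],
                 offset = as.integer(pos), strand = strand)
    })
    do.call(rbind, hits)
  }
  out <- scan_one(full, "+")
  if (revcomp)
    out <- rbind(out, scan_one(revcomp_dna(full), "-"))
  if (is.null(out))
    out <- data.frame(factor = character(), site = character(),
                      offset = integer(), strand = character())
  out[order(out$offset, out$factor), , drop = FALSE]
}

revcomp_dna <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(x), "")[[1]]),
                               collapse = ""))
}

#' Site differences between wildtype and a variant
#'
#' Set differences of [scan_sites()] results by (factor, site) pair:
#' `deleted` = present in wildtype, absent in variant; `created` = present
#' in variant, absent in wildtype; `retained` = present in both.
#'
#' @param wildtype,variant core sequences.
#' @param catalog a [site_catalog()].
#' @param ... passed to [scan_sites()] (contexts, strand flag).
#' @return List of data frames `deleted`, `created`, `retained` with
#'   columns `factor`, `site`.
#' @export
diff_sites <- function(wildtype, variant, catalog, ...) {
  key <- function(seq) {
    h <- scan_sites(seq, catalog, ...)
    unique(h[, c("factor", "site")])
  }
  wt <- key(wildtype); vr <- key(variant)
  kw <- paste(wt$factor, wt$site); kv <- paste(vr$factor, vr$site)
  list(deleted = wt[!(kw %in% kv), , drop = FALSE],
       created = vr[!(kv %in% kw), , drop = FALSE],
       retained = wt[kw %in% kv, , drop = FALSE])
}

#' Match a southwestern band to candidate factors by size
#'
#' Returns the factors with any cataloged molecular weight inside the
#' closed interval band +/- `tolerance` * band (default +/-10 percent of
#' the observed band size).
#'
#' @param band_kda observed band size in kDa (> 0).
#' @param catalog a [site_catalog()].
#' @param tolerance relative tolerance (0.1 = 10 percent).
#' @return Character vector of candidate factor names.
#' @export
match_band_to_tf <- function(band_kda, catalog, tolerance = 0.1) {
  stopifnot(band_kda > 0, tolerance >= 0)
  lo <- band_kda * (1 - tolerance)
  hi <- band_kda * (1 + tolerance)
  fac <- unique(catalog$factor)
  fac[vapply(fac, function(f) {
    mws <- unlist(catalog$mw[catalog$factor == f])
    any(mws >= lo & mws <= hi)
  }, logical(1))]
}
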