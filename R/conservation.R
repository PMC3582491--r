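#' Taxonomic working weights
#'
#' Converts integer base weights (assigned as each clade joins the guide
#' tree, larger for densely sampled clades) into per-species working
#' weights w = 2^(1 / base_weight), max-normalized within the analysis
#' scope so the highest working weight is exactly 1. The mild
#' down-weighting partially compensates for over-representation of some
#' clades in the alignment.
#'
#' @param tax data frame with columns `species`, `group`, `base_weight`
#'   (positive integers).
#' @param scope a clade scope: one of `"primates"`, `"euarchontoglires"`,
#'   `"boreoeutheria"`, `"eutheria"`, `"mammals"`, or a character vector of
#'   `group` values to include.
#' @return Named vector of working weights in (0, 1] for the species in
#'   scope (attribute `scope` records the request).
#' @examples
#' tax <- data.frame(species = c("human", "opossum"),
#'                   group = c("primates", "marsupials"),
#'                   base_weight = c(11, 1))
#' working_weights(tax, "mammals")
#' @export
working_weights <- function(tax, scope = "mammals") {
  stopifnot(all(c("species", "group", "base_weight") %in% names(tax)))
  if (any(tax$base_weight < 1)) stop("base weights must be >= 1")
  groups <- clade_scope_groups(scope, tax$group)
  sel <- tax[tax$group %in% groups, ]
  if (!nrow(sel)) stop("scope '", paste(scope, collapse = "+"),
                       "' selects no species")
  raw <- 2^(1 / sel$base_weight)
  w <- raw / max(raw)
  names(w) <- sel$species
  attr(w, "scope") <- scope
  w
}

# Nested clade scopes: primates < euarchontoglires < boreoeutheria <
# eutheria < mammals, expressed over the innermost `group` labels.
clade_scope_groups <- function(scope, available) {
  nested <- list(
    primates = "primates",
    euarchontoglires = c("primates", "glires"),
    boreoeutheria = c("primates", "glires", "laurasiatheria"),
    eutheria = c("primates", "glires", "laurasiatheria", "atlantogenata"),
    mammals = c("primates", "glires", "laurasiatheria", "atlantogenata",
                "marsupials"))
  if (length(scope) == 1 && scope %in% names(nested))
    return(intersect(nested[[scope]], unique(available)))
  unknown <- setdiff(scope, unique(available))
  if (length(unknown))
    stop("unknown clade group(s): ", paste(unknown, collapse = ", "))
  scope
}

#' Weighted information content of one alignment column
#'
#' Weighted base frequencies are computed over the non-gap residues
#' (weights renormalized to the non-gap rows) and the information content
#' is R_i = 2 + sum_b p_b log2 p_b bits: 2 bits for a fully conserved
#' column, 0 bits for an equal distribution of all four bases. No
#' small-sample correction is applied. The optional bootstrap resamples
#' species rows (with their weights) to estimate the SD of R_i.
#'
#' @param residues character vector of residues (one per species).
#' @param weights working weights, same order as `residues`; default equal.
#' @param boot bootstrap repetitions for the SD of R_i (0 disables).
#' @param seed seed for the bootstrap.
#' @return List with `p` (named base frequencies), `info` (bits), `sd`
#'   (or `NA` without bootstrap) and `weight_sum` (effective non-gap
#'   weight).
#' @export
column_info <- function(residues, weights = NULL, boot = 0, seed = 1) {
  residues <- toupper(residues)
  if (is.null(weights)) weights <- rep(1, length(residues))
  stopifnot(length(weights) == length(residues), all(weights > 0))
  ok <- residues %in% c("A", "C", "G", "T")
  if (sum(ok) < 2)
    stop("undefined column: fewer than 2 non-gap residues")
  p <- weighted_base_freq(residues[ok], weights[ok])
  info <- info_bits(p)
  sd_ri <- NA_real_
  if (boot > 0) {
    set.seed(seed)
    n <- length(residues)
    vals <- numeric(boot)
    kept <- 0L
    for (b in seq_len(boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- residues[idx]; w <- weights[idx]
      keep <- r %in% c("A", "C", "G", "T")
      if (sum(keep) < 2) next
      kept <- kept + 1L
      vals[kept] <- info_bits(weighted_base_freq(r[keep], w[keep]))
    }
    sd_ri <- if (kept > 1) stats::sd(vals[seq_len(kept)]) else NA_real_
  }
  list(p = p, info = info, sd = sd_ri, weight_sum = sum(weights[ok]))
}

weighted_base_freq <- function(residues, weights) {
  p <- vapply(c("A", "C", "G", "T"),
              function(b) sum(weights[residues == b]), numeric(1))
  p / sum(p)
}

info_bits <- function(p) {
  nz <- p[p > 0]
  2 + sum(nz * log2(nz))
}

# Per-column information for a set of columns; NA where a column has
# fewer than 2 non-gap residues (flagged undefined, excluded downstream).
alignment_info <- function(aln, weights, columns = seq_len(ncol(aln$seq))) {
  mat <- aln$seq[names(weights), columns, drop = FALSE]
  vapply(seq_along(columns), function(j) {
    r <- mat[, j]
    ok <- r %in% c("A", "C", "G", "T")
    if (sum(ok) < 2) return(NA_real_)
    info_bits(weighted_base_freq(r[ok], weights[ok]))
  }, numeric(1))
}

#' Sliding-window conservation track
#'
#' Mean per-column information content in a sliding window (default 100
#' nt, roughly the internucleosomal spacing of chromosomal DNA) over the
#' columns that are usable, i.e. not gapped across all rows of the masking
#' clade (default the primates): clade-specific insertions therefore do
#' not dilute the track. The confidence interval is a t-interval over the
#' per-column values inside the window; `bonferroni_m` widens it for
#' simultaneous clade-level contrasts.
#'
#' @param aln a [promoter_alignment()].
#' @param weights working weights (see [working_weights()]); rows not in
#'   `names(weights)` are ignored.
#' @param window window width in usable columns.
#' @param conf_level nominal confidence level.
#' @param bonferroni_m number of simultaneous comparisons to adjust for
#'   (1 = none).
#' @param mask_clade `group` label(s) whose all-gap columns are skipped;
#'   `NULL` uses every column with a defined R_i.
#' @return Data frame with `center` (promoter coordinate of the window's
#'   central usable column), `mean_bits`, `ci_lo`, `ci_hi`, `n_columns`.
#' @export
window_track <- function(aln, weights, window = 100, conf_level = 0.95,
                         bonferroni_m = 1, mask_clade = "primates") {
  stopifnot(inherits(aln, "promoter_alignment"))
  usable <- seq_len(ncol(aln$seq))
  if (!is.null(mask_clade) && !is.null(aln$taxonomy)) {
    sp <- aln$taxonomy$species[aln$taxonomy$group %in% mask_clade]
    sp <- intersect(sp, rownames(aln$seq))
    if (length(sp)) {
      allgap <- colSums(aln$seq[sp, , drop = FALSE] != "-") == 0
      usable <- usable[!allgap]
    }
  }
  ri <- alignment_info(aln, weights, usable)
  usable <- usable[!is.na(ri)]
  ri <- ri[!is.na(ri)]
  if (window > length(usable))
    stop("window larger than the number of usable columns")
  alpha <- (1 - conf_level) / max(1, bonferroni_m)
  nwin <- length(usable) - window + 1
  out <- data.frame(center = integer(nwin), mean_bits = numeric(nwin),
                    ci_lo = numeric(nwin), ci_hi = numeric(nwin),
                    n_columns = window)
  tcrit <- stats::qt(1 - alpha / 2, df = window - 1)
  half_idx <- floor(window / 2)
  for (i in seq_len(nwin)) {
    v <- ri[i:(i + window - 1)]
    m <- mean(v)
    hw <- tcrit * stats::sd(v) / sqrt(window)
    cen_col <- usable[i + half_idx]
    cen <- aln$ref_coord[cen_col]
    if (is.na(cen)) {  # reference gapped at the centre: nearest mapped col
      mapped <- which(!is.na(aln$ref_coord))
      cen <- aln$ref_coord[mapped[which.min(abs(mapped - cen_col))]]
    }
    out$center[i] <- cen
    out$mean_bits[i] <- m
    out$ci_lo[i] <- m - hw
    out$ci_hi[i] <- m + hw
  }
  out
}

#' Taxonomically weighted homology to the reference
#'
#' For each column of the region, the weighted fraction of species whose
#' residue equals the reference residue (a gap counts as a mismatch); the
#' region value is the mean over columns, with its standard error over
#' columns.
#'
#' @param aln a [promoter_alignment()].
#' @param region region name or coordinate pair (see [region_columns()]).
#' @param weights working weights; the species scored are `names(weights)`.
#' @param reference reference species (default the alignment's).
#' @return List with `homology` and `se`, both in percent.
#' @export
weighted_homology <- function(aln, region = "PRE", weights,
                              reference = aln$reference) {
  cols <- region_columns(aln, region)
  ref <- aln$seq[reference, cols]
  if (any(ref == "-"))
    stop("reference has undefined residues within the region")
  mat <- aln$seq[names(weights), cols, drop = FALSE]
  wsum <- sum(weights)
  percol <- vapply(seq_along(cols), function(j)
    sum(weights[mat[, j] == ref[j]]) / wsum, numeric(1))
  list(homology = 100 * mean(percol),
       se = 100 * stats::sd(percol) / sqrt(length(percol)))
}

#' Sequence-logo matrix for a region
#'
#' Per-column letter heights p_b * R_i (heights sum to the column's
#' information content) with bootstrap SD error bars from [column_info()].
#'
#' @param aln a [promoter_alignment()].
#' @param region region name or coordinate pair.
#' @param weights working weights.
#' @param boot bootstrap repetitions for the per-column SD of R_i.
#' @param seed bootstrap seed.
#' @return Data frame with `coord`, heights `A`, `C`, `G`, `T`, `info`
#'   and `sd`.
#' @export
logo_matrix <- function(aln, region = "PRE", weights, boot = 1000,
                        seed = 1) {
  cols <- region_columns(aln, region)
  mat <- aln$seq[names(weights), cols, drop = FALSE]
  rows <- lapply(seq_along(cols), function(j) {
    ci <- column_info(mat[, j], weights, boot = boot, seed = seed + j)
    data.frame(coord = aln$ref_coord[cols[j]],
               A = ci$p["A"] * ci$info, C = ci$p["C"] * ci$info,
               G = ci$p["G"] * ci$info, T = ci$p["T"] * ci$info,
               info = ci$info, sd = ci$sd, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Clade-level region summaries
#'
#' Total information content (sum of per-column R_i over the region, with
#' a species-bootstrap SD) and weighted homology to the reference, for a
#' set of nested clade scopes.
#'
#' @param aln a [promoter_alignment()] carrying a taxonomy.
#' @param region region name or coordinate pair.
#' @param scopes clade scopes (see [working_weights()]).
#' @param boot bootstrap repetitions for the SD of the R_i total.
#' @param seed bootstrap seed.
#' @return Data frame with one row per scope: `scope`, `n`, `ri_total`,
#'   `ri_sd`, `homology`, `homology_se`.
#' @export
region_summary <- function(aln, region = "PRE",
                           scopes = c("primates", "euarchontoglires",
                                      "boreoeutheria", "eutheria",
                                      "mammals"),
                           boot = 200, seed = 1) {
  stopifnot(!is.null(aln$taxonomy))
  cols <- region_columns(aln, region)
  out <- lapply(scopes, function(sc) {
    w <- working_weights(aln$taxonomy, sc)
    w <- w[intersect(names(w), rownames(aln$seq))]
    ri <- alignment_info(aln, w, cols)
    total <- sum(ri, na.rm = TRUE)
    set.seed(seed)
    mat <- aln$seq[names(w), cols, drop = FALSE]
    tot_b <- numeric(boot)
    for (b in seq_len(boot)) {
      idx <- sample.int(length(w), length(w), replace = TRUE)
      tot_b[b] <- sum(vapply(seq_along(cols), function(j) {
        r <- mat[idx, j]; wb <- w[idx]
        ok <- r %in% c("A", "C", "G", "T")
        if (sum(ok) < 2) return(NA_real_)
        info_bits(weighted_base_freq(r[ok], wb[ok]))
      }, numeric(1)), na.rm = TRUE)
    }
    hom <- weighted_homology(aln, region, w)
    data.frame(scope = sc, n = length(w), ri_total = total,
               ri_sd = stats::sd(tot_b), homology = hom$homology,
               homology_se = hom$se)
  })
  do.call(rbind, out)
}
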