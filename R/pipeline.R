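#' Run stages and write report bundles
#'
#' Thin orchestration layer over the analysis stages. Each `run_*`
#' function reads standard input formats (TSV, aligned FASTA, newick),
#' executes the corresponding stage, writes a TSV report plus a JSON
#' summary embedding the full resolved configuration, and returns the
#' result invisibly. Outputs are deterministic given the configuration
#' and seed; no stage mutates its inputs.
#'
#' @param input path to an assay TSV (see [read_assay_tsv()]).
#' @param control control variant label.
#' @param alpha test level.
#' @param boxcox `"auto"` or `"never"` (ratio assays).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the per-assay [effect_size_analysis()] results.
#' @name pipeline
#' @export
run_effectsize <- function(input, control, alpha = 0.05,
                           boxcox = "auto", out_dir = ".") {
  tabs <- read_assay_tsv(input, control = control)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- lapply(tabs, effect_size_analysis, alpha = alpha,
                boxcox = boxcox)
  for (es in res) {
    utils::write.table(es$table,
                       file.path(out_dir, paste0(es$assay_id, "_effects.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- lapply(res, function(es) list(
    assay_id = es$assay_id, kind = es$kind, control = es$control,
    F = es$anova$F, p = es$anova$p, ms_error = es$anova$ms_error,
    psi = es$psi, dunnett_critical = es$dunnett_critical,
    transform_lambda = es$transform_lambda,
    flagged = es$table$variant[es$table$dunnett]))
  write_report_json(list(stage = "effectsize",
                         config = list(input = input, control = control,
                                       alpha = alpha, boxcox = boxcox),
                         assays = summary),
                    file.path(out_dir, "effectsize_report.json"))
  invisible(res)
}

#' @rdname pipeline
#' @param pairs path to a TSV with columns `variant`, `g_x`, `g_y` (or an
#'   [effect_pairs()] object).
#' @param pairs2 optional second pair set for the distribution-overlap
#'   comparison.
#' @param boot_reps bootstrap repetitions.
#' @param seed mandatory seed for the bootstrap.
#' @param bins histogram bins for [overlap_pct()].
#' @export
run_metacorr <- function(pairs, pairs2 = NULL, boot_reps = 100000, seed,
                         bins = 50, out_dir = ".") {
  read_pairs <- function(p) {
    if (inherits(p, "effect_pairs")) return(p)
    d <- utils::read.delim(p, stringsAsFactors = FALSE)
    effect_pairs(d$g_x, d$g_y, labels = d$variant)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- read_pairs(pairs)
  ba <- bootstrap_r(a, B = boot_reps, seed = seed)
  out <- list(stage = "metacorr",
              config = list(boot_reps = boot_reps, seed = seed,
                            bins = bins),
              r = ba$r_observed, p = ba$p, B = ba$B,
              n_degenerate = ba$n_degenerate)
  if (!is.null(pairs2)) {
    b <- read_pairs(pairs2)
    bb <- bootstrap_r(b, B = boot_reps, seed = seed + 1)
    out$r2 <- bb$r_observed
    out$p2 <- bb$p
    out$overlap_pct <- overlap_pct(ba$r, bb$r, bins = bins)
  }
  write_report_json(out, file.path(out_dir, "metacorr_report.json"))
  invisible(out)
}

#' @rdname pipeline
#' @param aln path to an aligned multi-FASTA.
#' @param taxonomy path to the species metadata TSV.
#' @param reference reference species name.
#' @param scope clade scope for the weights.
#' @param window window width for the conservation track.
#' @param region region coordinates `c(from, to)` for summaries/logos.
#' @param first_coord coordinate of the reference row's first base.
#' @export
run_conserve <- function(aln, taxonomy, reference, scope = "mammals",
                         window = 100, region = c(-76, -47),
                         first_coord = -326L, seed = 1, out_dir = ".") {
  pa <- read_promoter_alignment(aln, taxonomy, reference = reference,
                                first_coord = first_coord,
                                regions = list(region = as.integer(region)))
  w <- working_weights(pa$taxonomy, scope)
  w <- w[intersect(names(w), rownames(pa$seq))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- window_track(pa, w, window = window)
  utils::write.table(tr, file.path(out_dir, "window_track.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  lg <- logo_matrix(pa, "region", w, seed = seed)
  utils::write.table(lg, file.path(out_dir, "logo_matrix.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  hom <- weighted_homology(pa, "region", w)
  ri <- alignment_info(pa, w, region_columns(pa, "region"))
  write_report_json(list(stage = "conserve",
                         config = list(aln = aln, taxonomy = taxonomy,
                                       reference = reference,
                                       scope = scope, window = window,
                                       region = region, seed = seed),
                         ri_total = sum(ri, na.rm = TRUE),
                         homology = hom$homology,
                         homology_se = hom$se),
                    file.path(out_dir, "conserve_report.json"))
  invisible(list(track = tr, logo = lg, homology = hom))
}

#' @rdname pipeline
#' @param tree path to a newick tree with branch lengths.
#' @param clade_a,clade_b tip sets defining the rooting split.
#' @param m number of comparisons for the Bonferroni adjustment.
#' @export
run_clock <- function(tree, clade_a, clade_b = NULL, alpha = 0.05,
                      m = NULL, out_dir = ".") {
  tr <- ape::read.tree(tree)
  rooted <- root_between(tr, clade_a, clade_b)
  d <- root_to_tip(rooted)
  if (is.null(m)) m <- length(d)
  rep <- clock_outliers(d, alpha = alpha, m = m)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(rep),
                     file.path(out_dir, "clock_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_report_json(list(stage = "clock",
                         config = list(tree = tree, alpha = alpha, m = m),
                         mean_distance = attr(rep, "mean"),
                         half_width = attr(rep, "half_width"),
                         n_faster = sum(rep$class == "faster"),
                         n_slower = sum(rep$class == "slower")),
                    file.path(out_dir, "clock_report.json"))
  invisible(rep)
}

#' @rdname pipeline
#' @param catalog path to a site-catalog TSV (columns `factor`, `site`,
#'   `mw`) or a [site_catalog()].
#' @param variants named character vector of variant core sequences, or a
#'   TSV with columns `variant`, `sequence`.
#' @param wildtype name of the wildtype entry in `variants`.
#' @param context_3p 3' context appended when scanning.
#' @export
run_sitescan <- function(catalog, variants, wildtype = "PRE",
                         context_3p = pre_plasmid_context(),
                         out_dir = ".") {
  if (!inherits(catalog, "site_catalog"))
    catalog <- site_catalog(utils::read.delim(catalog,
                                              stringsAsFactors = FALSE))
  if (is.character(variants) && length(variants) == 1 &&
      file.exists(variants)) {
    d <- utils::read.delim(variants, stringsAsFactors = FALSE)
    variants <- stats::setNames(d$sequence, d$variant)
  }
  stopifnot(wildtype %in% names(variants))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (v in setdiff(names(variants), wildtype)) {
    d <- diff_sites(variants[[wildtype]], variants[[v]], catalog,
                    context_3p = context_3p)
    for (status in c("deleted", "created", "retained")) {
      x <- d[[status]]
      if (nrow(x))
        rows[[length(rows) + 1]] <-
          data.frame(variant = v, factor = x$factor, site = x$site,
                     status = status)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), factor = character(),
               site = character(), status = character())
  utils::write.table(out, file.path(out_dir, "sitescan_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_report_json(list(stage = "sitescan",
                         config = list(wildtype = wildtype,
                                       context_3p = context_3p),
                         n_variants = length(variants) - 1),
                    file.path(out_dir, "sitescan_report.json"))
  invisible(out)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}
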