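#' Simulate film densitometry for a variant panel
#'
#' Generates triplicate-style band-density readings with film-level offset
#' and scale effects and Gaussian residual noise:
#' signal = offset_f + scale_f * (mu_j + eps), eps ~ N(0, resid_sd),
#' where mu_j = delta_j * resid_sd encodes the true standardized effect of
#' variant j. Each film carries every variant. Deterministic given the
#' seed.
#'
#' @param seed mandatory integer seed.
#' @param k number of variants (control plus k - 1 mutants).
#' @param films number of films; with `n_per_film` replicates each, every
#'   variant has `films * n_per_film` replicates in total.
#' @param n_per_film replicates of each variant within a film.
#' @param delta true standardized effects, length k (control first,
#'   conventionally 0).
#' @param film_offset_sd SD of the additive film offset.
#' @param film_scale_sd SD of the multiplicative film scale around 1.
#' @param resid_sd residual SD (density units).
#' @param control control variant label.
#' @return An [assay_table()] of kind `"subtractive"`.
#' @export
gen_densitometry <- function(seed, k = 8, films = 3, n_per_film = 1,
                             delta = rep(0, k), film_offset_sd = 0.5,
                             film_scale_sd = 0.1, resid_sd = 1,
                             control = "PRE") {
  if (missing(seed)) stop("a seed is required")
  stopifnot(length(delta) == k, film_offset_sd >= 0, film_scale_sd >= 0,
            resid_sd > 0)
  set.seed(seed)
  variants <- c(control, paste0("M", seq_len(k - 1)))
  mu <- delta * resid_sd
  rows <- list()
  for (f in seq_len(films)) {
    off <- stats::rnorm(1, 0, film_offset_sd)
    scl <- stats::rnorm(1, 1, film_scale_sd)
    for (r in seq_len(n_per_film)) {
      eps <- stats::rnorm(k, 0, resid_sd)
      rows[[length(rows) + 1]] <-
        data.frame(film = paste0("film", f), variant = variants,
                   replicate = r, signal = off + scl * (mu + eps))
    }
  }
  assay_table(do.call(rbind, rows), kind = "subtractive",
              control = control, assay_id = paste0("sim_densitometry_",
                                                   seed))
}

#' Simulate reporter ELISA measurements with a cotransfection covariate
#'
#' Ratio-scale reporter signals with multiplicative lognormal noise around
#' the true expression ratios, scaled by an independent positive
#' transfection-efficiency covariate that the normalization step divides
#' out.
#'
#' @param seed mandatory integer seed.
#' @param ratios true expression ratios relative to control (control
#'   first, = 1).
#' @param sigma lognormal noise SD (log scale).
#' @param covariate_range uniform range of the positive covariate.
#' @param n replicates per variant.
#' @param control control variant label.
#' @return An [assay_table()] of kind `"ratio"` with a `covariate` column.
#' @export
gen_reporter <- function(seed, ratios = rep(1, 8), sigma = 0.2,
                         covariate_range = c(0.5, 2), n = 3,
                         control = "PRE") {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(ratios > 0), sigma >= 0, all(covariate_range > 0))
  set.seed(seed)
  k <- length(ratios)
  variants <- c(control, paste0("M", seq_len(k - 1)))
  rows <- list()
  for (r in seq_len(n)) {
    cov <- stats::runif(k, covariate_range[1], covariate_range[2])
    sig <- ratios * exp(stats::rnorm(k, 0, sigma)) * cov
    rows[[length(rows) + 1]] <-
      data.frame(film = paste0("batch", r), variant = variants,
                 replicate = r, signal = sig, covariate = cov)
  }
  assay_table(do.call(rbind, rows), kind = "ratio", control = control,
              assay_id = paste0("sim_reporter_", seed))
}

#' Simulate a clade-structured promoter alignment
#'
#' Evolves an ancestral sequence down a fixed nested guide topology
#' (five clades joining as marsupials, atlantogenata, laurasiatheria,
#' glires and primates, mirroring a mammal-wide sampling design) by
#' uniform-replacement (Jukes-Cantor-style) substitution. A conserved
#' block substitutes at `block_multiplier` times the flanking rate;
#' multiplier 0 freezes the block, multiplier 1 makes it
#' indistinguishable from the flanks. Optionally a marsupial-specific
#' insertion is placed inside the block (gap columns in all other
#' species).
#'
#' @param seed mandatory integer seed.
#' @param clade_sizes named sizes of the five clades.
#' @param n_sites ancestral (reference) sequence length.
#' @param first_coord promoter coordinate of the first position.
#' @param sub_prob substitution probability per site per unit branch
#'   length.
#' @param block 2-vector of promoter coordinates of the conserved block.
#' @param block_multiplier rate multiplier inside the block (>= 0).
#' @param marsupial_insertion length of a marsupial-specific insertion
#'   inside the block (0 = none).
#' @param branch_scale overall branch-length scale.
#' @return A [promoter_alignment()] whose taxonomy carries per-clade base
#'   weights equal to the clade sizes.
#' @export
gen_alignment <- function(seed,
                          clade_sizes = c(primates = 9, glires = 9,
                                          laurasiatheria = 9,
                                          atlantogenata = 5,
                                          marsupials = 3),
                          n_sites = 529, first_coord = -326L,
                          sub_prob = 0.06, block = c(-76L, -47L),
                          block_multiplier = 0.25,
                          marsupial_insertion = 0, branch_scale = 1) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(sub_prob >= 0, sub_prob <= 1, block_multiplier >= 0,
            branch_scale > 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n_sites, replace = TRUE)
  coords <- promoter_coords(first_coord, n_sites)
  in_block <- coords >= block[1] & coords <= block[2]
  site_rate <- ifelse(in_block, sub_prob * block_multiplier, sub_prob)
  mutate <- function(s, len) {
    p <- pmin(1, site_rate * len * branch_scale)
    hit <- stats::runif(length(s)) < p
    if (any(hit)) {
      cur <- s[hit]
      s[hit] <- vapply(cur, function(b)
        sample(setdiff(bases, b), 1), character(1))
    }
    s
  }
  # nested guide topology with unit stems and unit terminal branches:
  # (marsupials, (atlantogenata, (laurasiatheria, (glires, primates))))
  stems <- list(marsupials = 2, atlantogenata = 2, laurasiatheria = 2,
                glires = 1, primates = 1)
  backbone <- c(marsupials = 0, atlantogenata = 1, laurasiatheria = 2,
                glires = 3, primates = 3)
  seqs <- list(); groups <- character(0)
  node_cache <- list()
  for (cl in names(clade_sizes)) {
    s <- anc
    for (step in seq_len(backbone[[cl]])) {
      key <- paste0("bb", step)
      if (is.null(node_cache[[key]]))
        node_cache[[key]] <- mutate(if (step == 1) anc else
          node_cache[[paste0("bb", step - 1)]], 1)
      s <- node_cache[[key]]
    }
    s <- mutate(s, stems[[cl]])
    for (i in seq_len(clade_sizes[[cl]])) {
      nm <- sprintf("%s_%02d", cl, i)
      seqs[[nm]] <- paste(mutate(s, 1), collapse = "")
      groups <- c(groups, cl)
    }
  }
  seqs <- unlist(seqs)
  tax <- data.frame(species = names(seqs), group = groups,
                    base_weight = unname(clade_sizes[groups]))
  if (marsupial_insertion > 0) {
    blk_cols <- which(in_block)
    at <- blk_cols[ceiling(length(blk_cols) / 2)]
    ins <- replicate(sum(groups == "marsupials"),
                     paste(sample(bases, marsupial_insertion,
                                  replace = TRUE), collapse = ""))
    is_mar <- groups == "marsupials"
    fill <- rep(strrep("-", marsupial_insertion), length(seqs))
    fill[is_mar] <- ins
    seqs <- paste0(substr(seqs, 1, at), fill,
                   substr(seqs, at + 1, nchar(seqs)))
    names(seqs) <- tax$species
  }
  promoter_alignment(seqs, reference = "primates_01",
                     first_coord = first_coord, taxonomy = tax,
                     regions = list(PRE = c(-76L, -47L),
                                    block = as.integer(block)))
}

#' Simulate a clock or rate-perturbed phylogeny
#'
#' Draws an ultrametric coalescent tree scaled to a given depth; under the
#' strict clock all root-to-tip distances are equal. Named rate
#' multipliers scale the terminal branches of individual tips, emulating
#' lineage-specific rate acceleration or slowdown.
#'
#' @param seed mandatory integer seed.
#' @param n_tips number of tips.
#' @param depth root-to-tip depth (substitutions/site).
#' @param rate_multipliers named vector of terminal-branch multipliers
#'   (names = tip labels), or `NULL`.
#' @return A rooted [ape::phylo] tree.
#' @export
gen_tree <- function(seed, n_tips = 35, depth = 0.5,
                     rate_multipliers = NULL) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_tips >= 3, depth > 0)
  set.seed(seed)
  tr <- ape::rcoal(n_tips)
  d0 <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d0
  if (!is.null(rate_multipliers)) {
    stopifnot(all(rate_multipliers > 0), !is.null(names(rate_multipliers)))
    for (tip in names(rate_multipliers)) {
      i <- match(tip, tr$tip.label)
      if (is.na(i)) stop("unknown tip '", tip, "'")
      e <- which(tr$edge[, 2] == i)
      tr$edge.length[e] <- tr$edge.length[e] * rate_multipliers[[tip]]
    }
  }
  tr
}
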