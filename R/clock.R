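#' Root a tree on the edge separating two clades
#'
#' Places a root on the single edge separating `clade_a` from `clade_b`
#' (both sides must be monophyletic on the unrooted tree), by default at
#' the edge midpoint. All pairwise tip-to-tip path lengths are preserved.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param clade_a tip labels on one side of the root.
#' @param clade_b tip labels on the other side; defaults to the remaining
#'   tips.
#' @param fraction position of the root along the separating edge,
#'   measured from the `clade_a` side (0.5 = midpoint).
#' @return A rooted `phylo` tree.
#' @export
root_between <- function(tree, clade_a, clade_b = NULL, fraction = 0.5) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  stopifnot(fraction > 0, fraction < 1)
  tips <- tree$tip.label
  if (is.null(clade_b)) clade_b <- setdiff(tips, clade_a)
  if (!setequal(c(clade_a, clade_b), tips) ||
      length(intersect(clade_a, clade_b)))
    stop("clade_a and clade_b must partition the tips")
  un <- ape::unroot(tree)
  rooted <- tryCatch(
    ape::root(un, outgroup = clade_a, resolve.root = TRUE),
    error = function(e)
      stop("non-monophyly error: no single edge separates the clades"))
  root_node <- ape::Ntip(rooted) + 1L
  basal <- which(rooted$edge[, 1] == root_node)
  if (length(basal) != 2)
    stop("non-monophyly error: no single edge separates the clades")
  # identify the basal edge leading toward clade_a
  a_side <- vapply(basal, function(e) {
    desc <- tips_below(rooted, rooted$edge[e, 2])
    setequal(desc, clade_a)
  }, logical(1))
  if (!any(a_side))
    stop("non-monophyly error: no single edge separates the clades")
  total <- sum(rooted$edge.length[basal])
  rooted$edge.length[basal[a_side]] <- fraction * total
  rooted$edge.length[basal[!a_side]] <- (1 - fraction) * total
  rooted
}

tips_below <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

#' Root-to-tip distances
#'
#' Sum of branch lengths from the root to each tip; equal across tips
#' under a strict molecular clock.
#'
#' @param tree a rooted [ape::phylo] tree with non-negative branch
#'   lengths.
#' @return Named numeric vector of distances (substitutions/site).
#' @export
root_to_tip <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Molecular-clock outlier classification
#'
#' Compares each tip's root-to-tip distance to the mean distance plus or
#' minus a Bonferroni-adjusted band: mean +/- t(1 - alpha/(2m), N - 1) *
#' SD of the distances. Tips above the band evolve "faster" than typical,
#' tips below it "slower".
#'
#' @param distances named vector from [root_to_tip()] (>= 3 tips).
#' @param alpha nominal family level.
#' @param m number of comparisons the band is adjusted for; defaults to
#'   the number of tips.
#' @return A `clock_report` data frame with `tip`, `distance`, `class`
#'   (`"faster"`, `"slower"`, `"typical"`); attributes `mean`,
#'   `half_width`, `alpha`, `m`.
#' @export
clock_outliers <- function(distances, alpha = 0.05,
                           m = length(distances)) {
  n <- length(distances)
  if (n < 3) stop("need at least 3 tips")
  mu <- mean(distances)
  s <- stats::sd(distances)
  hw <- if (s == 0) 0 else stats::qt(1 - alpha / (2 * m), df = n - 1) * s
  cls <- rep("typical", n)
  cls[distances > mu + hw] <- "faster"
  cls[distances < mu - hw] <- "slower"
  out <- data.frame(tip = names(distances), distance = unname(distances),
                    class = cls, row.names = NULL)
  attr(out, "mean") <- mu
  attr(out, "half_width") <- hw
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("clock_report", "data.frame")
  out
}
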