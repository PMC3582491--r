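toy_alignment <- function() {
  seqs <- c(hum = "ACGT-ACGTGG", chi = "ACGT-ACGTGG",
            mou = "ACGAGACGTCC", opo = "TCGAGACCTCC")
  tax <- data.frame(species = names(seqs),
                    group = c("primates", "primates", "glires",
                              "marsupials"),
                    base_weight = c(11, 10, 9, 1))
  promoter_alignment(seqs, reference = "hum", first_coord = -5L,
                     taxonomy = tax, regions = list(PRE = c(-2L, 2L)))
}

test_that("working weights follow 2^(1/base_weight) with max normalization", {
  tax <- pre_taxonomy()
  w <- working_weights(tax, "mammals")
  expect_equal(length(w), 35)
  expect_equal(max(w), 1)
  # the least-weighted clade member (base weight 1) is the scope maximum
  expect_equal(unname(w["Mondelphis domestica"]), 1)
  expect_equal(unname(w["Homo sapiens"]), 2^(1 / 11) / 2, tolerance = 1e-12)
  # equal base weights give all working weights 1
  tax2 <- data.frame(species = c("a", "b"), group = "primates",
                     base_weight = c(4, 4))
  expect_equal(unname(working_weights(tax2, "primates")), c(1, 1),
               ignore_attr = TRUE)
  tax2$base_weight <- c(0, 4)
  expect_error(working_weights(tax2, "primates"), ">= 1")
  # nested scopes select nested species sets
  expect_equal(length(working_weights(tax, "primates")), 9)
  expect_equal(length(working_weights(tax, "euarchontoglires")), 18)
  expect_equal(length(working_weights(tax, "boreoeutheria")), 27)
  expect_equal(length(working_weights(tax, "eutheria")), 32)
})

test_that("column information spans 0 to 2 bits with the textbook limits", {
  # fully conserved column: the maximum possible 2 bits
  expect_equal(column_info(c("G", "G", "G", "G"))$info, 2)
  # equal distribution of all four bases: 0 bits
  expect_equal(column_info(c("A", "C", "G", "T"))$info, 0)
  # two bases at half frequency: 1 bit
  expect_equal(column_info(c("A", "A", "C", "C"))$info, 1)
  # weights move the frequencies
  ci <- column_info(c("A", "C"), weights = c(3, 1))
  expect_equal(unname(ci$p["A"]), 0.75)
  # gaps carry no frequency mass
  ci2 <- column_info(c("A", "-", "A", "-"), weights = rep(1, 4))
  expect_equal(ci2$info, 2)
  expect_error(column_info(c("A", "-", "-")), "undefined column")
  # bootstrap SD is zero for a fully conserved column
  expect_equal(column_info(rep("T", 6), boot = 50)$sd, 0)
})

test_that("entropy merging property: pooling residue classes never lowers information", {
  set.seed(3)
  for (i in 1:20) {
    p <- as.vector(stats::rmultinom(1, 40, runif(4, 0.05, 1))) / 40
    info4 <- 2 + sum(ifelse(p > 0, p * log2(p), 0))
    pm <- c(p[1] + p[2], p[3], p[4])  # merge two classes
    info3 <- 2 + sum(ifelse(pm > 0, pm * log2(pm), 0))
    expect_gte(info3 + 1e-12, info4)
  }
})

test_that("coordinate mapping is a bijection that skips position 0", {
  aln <- toy_alignment()
  # reference: ACGT-ACGTGG has 10 ungapped bases from -5: -5..-1,+1..+5
  expect_equal(map_coords(aln, -5), 1)
  expect_equal(map_coords(aln, -1), 6)   # column 5 is a reference gap
  expect_equal(map_coords(aln, 1), 7)
  expect_error(map_coords(aln, 0), "no position 0")
  expect_error(map_coords(aln, 99), "outside")
  mapped <- map_coords(aln, promoter_coords(-5, 10))
  expect_equal(column_coord(aln, mapped), promoter_coords(-5, 10))
  expect_true(is.na(column_coord(aln, 5)))
  # a 30-position promoter region spans coordinates -76..-47
  expect_equal(length(promoter_span(-76, -47)), 30)
  # region resolution returns exactly the in-region reference columns
  expect_equal(region_columns(aln, "PRE"), c(4, 6, 7, 8))
})

test_that("weighted homology matches hand computation and self-comparison is 100%", {
  seqs <- c(ref = strrep("A", 30),
            oth = paste0(strrep("A", 27), "CCC"))
  aln <- promoter_alignment(seqs, "ref", first_coord = 1L,
                            regions = list(PRE = c(1L, 30L)))
  w <- c(ref = 1, oth = 1)
  h <- weighted_homology(aln, "PRE", w)
  # 3 mismatching columns at weighted fraction 1/2 each: 95% overall
  expect_equal(h$homology, 95)
  # reference against itself only
  expect_equal(weighted_homology(aln, "PRE", c(ref = 1))$homology, 100)
  # homology is bounded and gaps count as mismatch
  seqs2 <- c(ref = strrep("A", 10), gap = paste0(strrep("-", 5), strrep("A", 5)))
  aln2 <- promoter_alignment(seqs2, "ref", first_coord = 1L,
                             regions = list(PRE = c(1L, 10L)))
  expect_equal(weighted_homology(aln2, "PRE", c(ref = 1, gap = 1))$homology,
               75)
})

test_that("duplicating a species while halving its weight changes nothing", {
  aln <- gen_alignment(seed = 14, clade_sizes = c(primates = 4, glires = 3,
                                                  laurasiatheria = 3,
                                                  atlantogenata = 2,
                                                  marsupials = 2),
                       n_sites = 80, first_coord = -76L)
  w <- working_weights(aln$taxonomy, "mammals")
  cols <- region_columns(aln, "PRE")
  ri <- alignment_info(aln, w, cols)
  hom <- weighted_homology(aln, "PRE", w)

  dup <- rbind(aln$seq, aln$seq["glires_01", , drop = FALSE])
  rownames(dup)[nrow(dup)] <- "glires_dup"
  seqs2 <- apply(dup, 1, paste, collapse = "")
  tax2 <- rbind(aln$taxonomy,
                data.frame(species = "glires_dup", group = "glires",
                           base_weight = 3))
  aln2 <- promoter_alignment(seqs2, "primates_01", first_coord = -76L,
                             taxonomy = tax2)
  w2 <- w
  w2["glires_01"] <- w["glires_01"] / 2
  w2 <- c(w2, glires_dup = unname(w["glires_01"]) / 2)
  ri2 <- alignment_info(aln2, w2, cols)
  hom2 <- weighted_homology(aln2, "PRE", w2)
  expect_equal(ri2, ri, tolerance = 1e-12)
  expect_equal(hom2$homology, hom$homology, tolerance = 1e-12)

  # same invariance for logo letter heights
  lg <- logo_matrix(aln, "PRE", w, boot = 0)
  lg2 <- logo_matrix(aln2, "PRE", w2, boot = 0)
  expect_equal(lg2[, c("A", "C", "G", "T")], lg[, c("A", "C", "G", "T")],
               tolerance = 1e-12)
})

test_that("logo heights sum to the column information content", {
  aln <- gen_alignment(seed = 6, clade_sizes = c(primates = 3, glires = 3,
                                                 laurasiatheria = 2,
                                                 atlantogenata = 2,
                                                 marsupials = 2),
                       n_sites = 60, first_coord = -76L)
  w <- working_weights(aln$taxonomy, "mammals")
  lg <- logo_matrix(aln, "PRE", w, boot = 10, seed = 2)
  expect_equal(rowSums(lg[, c("A", "C", "G", "T")]), lg$info,
               tolerance = 1e-12)
  expect_true(all(lg$info >= 0 & lg$info <= 2))
  # a fully conserved column is a single letter of height 2
  one <- column_info(rep("G", 5))
  expect_equal(unname(one$p["G"] * one$info), 2)
})

test_that("the window track peaks over a conserved block and respects limits", {
  aln <- gen_alignment(seed = 20)
  w <- working_weights(aln$taxonomy, "mammals")
  tr <- window_track(aln, w, window = 100)
  expect_true(all(tr$mean_bits >= 0 & tr$mean_bits <= 2))
  expect_true(all(tr$ci_lo <= tr$mean_bits & tr$mean_bits <= tr$ci_hi))
  peak <- tr$center[which.max(tr$mean_bits)]
  expect_lt(abs(peak - (-61.5)), 50)  # block centre with a 100-nt window

  # frozen block: window means over the block reach higher than flanks
  aln0 <- gen_alignment(seed = 21, block_multiplier = 0)
  tr0 <- window_track(aln0, w, window = 30)
  expect_equal(max(tr0$mean_bits), 2, tolerance = 1e-12)

  # multiplier 1: no block contrast beyond noise
  aln1 <- gen_alignment(seed = 22, block_multiplier = 1)
  ri1 <- alignment_info(aln1, w)
  blk <- region_columns(aln1, "block")
  expect_lt(abs(mean(ri1[blk], na.rm = TRUE) -
                mean(ri1[-blk], na.rm = TRUE)), 0.25)
  expect_error(window_track(aln, w, window = 10000), "window larger")
})

test_that("window track skips columns gapped across the primates", {
  aln <- gen_alignment(seed = 30, marsupial_insertion = 9)
  w <- working_weights(aln$taxonomy, "mammals")
  # insertion columns are all-gap in primates and must be excluded
  ins_cols <- which(colSums(aln$seq[aln$taxonomy$group == "primates", ,
                                    drop = FALSE] != "-") == 0)
  expect_equal(length(ins_cols), 9)
  tr <- window_track(aln, w, window = 100)
  expect_true(all(tr$mean_bits >= 0 & tr$mean_bits <= 2))
  # homology over the block is depressed by the marsupial insertion
  h_mam <- weighted_homology(aln, "PRE", w)$homology
  h_eut <- weighted_homology(aln, "PRE",
                             working_weights(aln$taxonomy, "eutheria"))$homology
  expect_lt(h_mam, h_eut)
})

test_that("region summaries respect the information bound", {
  aln <- gen_alignment(seed = 40)
  rs <- region_summary(aln, "PRE", boot = 25, seed = 1)
  expect_true(all(rs$ri_total <= 2 * 30 + 1e-9))
  expect_true(all(rs$ri_total >= 0))
  expect_true(all(rs$homology >= 0 & rs$homology <= 100))
  expect_equal(rs$n, c(9, 18, 27, 32, 35))
})
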