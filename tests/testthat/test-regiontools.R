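test_that("TSS-relative offsets reproduce the minus-strand promoter arithmetic", {
  # nominal TSS of a minus-strand gene; promoter core interval contains it
  anch <- tss_anchor("chr1", 119530511L, "-", 119529911L, 119531245L)
  expect_equal(tss_relative(anch, 119531244L), -733L)
  expect_equal(tss_relative(anch, 119533033L), -2522L)
  expect_equal(tss_relative(anch, 119530511L), 0L)
  plus <- tss_anchor("chr1", 119530511L, "+", 119529911L, 119531245L)
  expect_equal(tss_relative(plus, 119530511L), 0L)
  expect_equal(tss_relative(plus, 119533033L), 2522L)
  expect_error(tss_relative(anch, 5L, chrom = "chr2"), "chr2")
})

test_that("TSS-relative mapping is a bijection on both strands", {
  set.seed(3)
  pos <- sample.int(2e6, 50)
  for (strand in c("+", "-")) {
    anch <- tss_anchor("chr1", 1000000L, strand, 999900L, 1000100L)
    off <- tss_relative(anch, pos)
    back <- if (strand == "+") anch$tss + off else anch$tss - off
    expect_identical(back, pos)
  }
})

test_that("DMRs classify as border, overlapping or distal around the promoter", {
  for (strand in c("+", "-")) {
    tss <- 100000L
    # promoter core -700..+600 in TSS-relative coordinates
    pstart <- if (strand == "+") tss - 700L else tss - 600L
    anch <- tss_anchor("chr1", tss, strand, pstart, pstart + 1300L)
    rel2gen <- function(a, b) {
      g <- if (strand == "+") c(tss + a, tss + b) else c(tss - b, tss - a)
      data.frame(chrom = "chr1", start = g[1L], end = g[2L])
    }
    expect_equal(classify_dmr_position(rel2gen(2600L, 4600L), anch),
                 "downstream_border")
    expect_equal(classify_dmr_position(rel2gen(-2600L, -1500L), anch),
                 "upstream_border")
    expect_equal(classify_dmr_position(rel2gen(-1000L, 1000L), anch),
                 "promoter_overlapping")
    expect_equal(classify_dmr_position(rel2gen(20000L, 21000L), anch),
                 "distal")
    expect_equal(classify_dmr_position(rel2gen(-30000L, -25000L), anch),
                 "distal")
    # border window boundary is inclusive
    expect_equal(classify_dmr_position(rel2gen(5300L, 6000L), anch,
                                       border_window = 5000L),
                 "downstream_border")
  }
  anch <- tss_anchor("chr1", 100000L, "+", 99300L, 100600L)
  expect_equal(classify_dmr_position(data.frame(chrom = "chr9",
                                                start = 1L, end = 10L), anch),
               "other_chromosome")
})

make_side <- function(meth, unmeth, pos = 100L, group = "A") {
  methylome_sample(paste0(group, meth), group,
                   cpg_sites("chr1", pos, as.integer(meth), as.integer(unmeth)))
}

test_that("regional comparison pools counts and applies Fisher's exact test", {
  a <- make_side(91L, 9L)
  b <- make_side(67L, 33L, group = "B")
  rc <- compare_region(c(0L, 1000L), a, b)
  expect_equal(rc$frac_a, 0.91)
  expect_equal(rc$frac_b, 0.67)
  expect_equal(rc$method, "fisher")
  expect_equal(rc$p, stats::fisher.test(rbind(c(91, 9), c(67, 33)))$p.value,
               tolerance = 1e-12)

  same <- compare_region(c(0L, 1000L), make_side(10L, 10L),
                         make_side(10L, 10L, group = "B"))
  expect_equal(same$p, 1)

  # doubling all counts keeps fractions, sharpens the p-value
  doubled <- compare_region(c(0L, 1000L), make_side(182L, 18L),
                            make_side(134L, 66L, group = "B"))
  expect_equal(doubled$frac_a, rc$frac_a)
  expect_lt(doubled$p, rc$p)

  expect_error(compare_region(c(5000L, 6000L), a, b), "side A")
})

test_that("the exact branch reproduces fisher.test across random tables", {
  set.seed(12)
  for (i in 1:300) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(methborder:::fisher_2x2(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("large totals fall back to chi-square and glm mode uses replicates", {
  big_a <- make_side(9100L, 900L)
  big_b <- make_side(6700L, 3300L, group = "B")
  rc <- compare_region(c(0L, 1000L), big_a, big_b)
  expect_equal(rc$method, "chisq")
  expect_lt(rc$p, 1e-10)

  a2 <- list(make_side(80L, 20L), make_side(85L, 15L))
  b2 <- list(make_side(40L, 60L, group = "B"), make_side(45L, 55L, group = "B"))
  rg <- compare_region(c(0L, 1000L), a2, b2, method = "glm")
  expect_true(rg$p > 0 && rg$p < 1e-5)
  expect_equal(rg$pooled_a, c(meth = 165, unmeth = 35))
})
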