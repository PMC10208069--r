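# Segregation chi-square, EM linkage, recombinant analysis, interval
# delimitation and panel concordance.

test_that("segregation chi-square matches the closed form and the printed anchor", {
  res <- chisq_segregation(191, 50)
  # independent closed-form oracle: sum((O - E)^2 / E) against chi2(1)
  expected <- c(3, 1) / 4 * 241
  chi_oracle <- sum((c(191, 50) - expected)^2 / expected)
  expect_equal(res$chi2, chi_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(chi_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(res$chi2, 2), 2.33)
  expect_equal(round(res$p_value, 2), 0.13)

  perfect <- chisq_segregation(183, 61)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)

  extreme <- chisq_segregation(0, 100)
  expect_equal(extreme$chi2, 300)
  expect_lt(extreme$p_value, 1e-10)

  expect_error(chisq_segregation(-1, 10), "non-negative")
})

test_that("recombination fractions: identical, unlinked and linked pairs", {
  mk2 <- data.frame(label = c("M1", "M2"), chrom = "chr6", pos = c(100, 200))
  same <- genotype_matrix(
    ids = sprintf("i%02d", 1:20), markers = mk2,
    codes = cbind(rep(c("A", "H", "B"), length.out = 20),
                  rep(c("A", "H", "B"), length.out = 20))
  )
  rf <- recombination_fractions(same)
  expect_equal(rf$r, 0, tolerance = 1e-9)
  expect_equal(rf$cM, 0, tolerance = 1e-6)

  # independent columns: r should approach 1/2 (cM flagged infinite)
  set.seed(71)
  draw <- function(n) c("A", "H", "H", "B")[sample.int(4, n, replace = TRUE)]
  unlinked <- genotype_matrix(
    ids = sprintf("i%04d", 1:1000), markers = mk2,
    codes = cbind(draw(1000), draw(1000))
  )
  rfu <- suppressWarnings(recombination_fractions(unlinked))
  expect_gt(rfu$r, 0.45)
  # a pair estimated at exactly r = 1/2 is flagged infinite and excluded
  mk3 <- data.frame(label = c("M1", "M2", "M3"), chrom = "c",
                    pos = c(1, 2, 3))
  rep_half <- genotype_matrix(
    sprintf("i%02d", 1:16), mk3,
    cbind(rep(c("A", "B"), 8), rep(c("A", "B"), each = 8),
          rep(c("A", "B"), each = 8))
  )
  expect_warning(rfh <- recombination_fractions(rep_half), "excluded")
  expect_true(is.infinite(rfh$cM[1L]))
  expect_equal(attr(rfh, "map_length_cM"), rfh$cM[2L])

  # simulated pair at a true distance of 5 cM, n = 847: recovered +- 1.5 cM
  mkr <- finemap_markers("chr6", 1e6, 2e6, n_markers = 2L, region_cM = 5)
  fam <- simulate_f3_family(mkr, 847L, causal_pos_bp = 1.5e6, seed = 72L)
  rf5 <- recombination_fractions(fam)
  expect_lt(abs(rf5$cM - 5), 1.5)
  # Kosambi gives a slightly shorter distance at the same r
  rfk <- recombination_fractions(fam, map_function = "kosambi")
  expect_lt(rfk$cM, rf5$cM)
})

test_that("regional map length is recovered at fine-mapping scale", {
  mk <- finemap_markers("chr6", 23.45e6, 24.22e6, n_markers = 21L,
                        region_cM = 6.7)
  fam <- simulate_f3_family(mk, 847L, causal_pos_bp = 23.8e6, seed = 73L)
  rf <- recombination_fractions(fam)
  len <- attr(rf, "map_length_cM")
  expect_lt(abs(len - 6.7) / 6.7, 0.3)
})

test_that("recombinants between flanking markers are exactly the planted ones", {
  mk <- data.frame(label = paste0("M", 1:4), chrom = "chr6",
                   pos = c(100, 200, 300, 400))
  codes <- rbind(
    c("A", "A", "A", "A"), # not recombinant
    c("B", "B", "B", "B"),
    c("H", "H", "H", "H"),
    c("A", "A", "H", "H"), # planted recombinant, breakpoint M2-M3
    c("B", "H", "H", "H"), # planted recombinant, breakpoint M1-M2
    c("A", NA, "A", "A"),
    c("A", "A", "A", NA), # missing at flank: excluded
    c("H", "H", "H", "H"),
    c("B", "B", "B", "B"),
    c("A", "A", "A", "A")
  )
  gm <- genotype_matrix(sprintf("i%02d", 1:10), mk, codes,
                        phenotype = rep("green", 10))
  rec <- find_recombinants(gm, "M1", "M4")
  expect_identical(rec$id, c("i04", "i05"))
  expect_identical(rec$breakpoints[[1L]],
                   data.frame(left = "M2", right = "M3",
                              stringsAsFactors = FALSE))
  expect_identical(rec$breakpoints[[2L]],
                   data.frame(left = "M1", right = "M2",
                              stringsAsFactors = FALSE))
  expect_error(find_recombinants(gm, "M1", "M9"), "not found")
})

test_that("single-recombinant delimitation follows the dominance rule", {
  mk <- data.frame(label = paste0("M", 1:4), chrom = "chr6",
                   pos = c(1000, 2000, 3000, 4000))
  # green A,A,H,H: green is consistent everywhere -> full span
  g_green <- genotype_matrix("r1", mk,
                             matrix(c("A", "A", "H", "H"), 1L),
                             phenotype = "green")
  iv <- delimit_interval("r1", g_green)
  expect_identical(iv$left_marker, "M1")
  expect_identical(iv$right_marker, "M4")

  # yellow B,B,H,H: causal must sit where the genotype is B -> right
  # bound at M3 (left of the B->H transition)
  g_yellow <- genotype_matrix("r1", mk,
                              matrix(c("B", "B", "H", "H"), 1L),
                              phenotype = "yellow")
  iv2 <- delimit_interval("r1", g_yellow)
  expect_identical(iv2$left_marker, "M1")
  expect_identical(iv2$right_marker, "M3")
  expect_identical(iv2$start, 1000)
  expect_identical(iv2$end, 3000)
})

test_that("a panel of recombinants delimits the planted interval", {
  # eight ordered markers; truth: causal in the (M5, M7) span.
  mk <- data.frame(label = paste0("M", 1:8), chrom = "chr6",
                   pos = seq(1000, 8000, by = 1000))
  codes <- rbind(
    c("B", "B", "B", "B", "B", "B", "H", "H"), # yellow, bp (M6,M7)
    c("H", "H", "H", "H", "H", "B", "B", "B"), # yellow, bp (M5,M6)
    c("A", "A", "H", "H", "H", "H", "H", "H"), # green, uninformative left
    c("B", "B", "H", "H", "H", "H", "H", "H"), # green (H at causal)
    c("H", "H", "H", "H", "H", "H", "B", "B"), # green -> causal not right of M7
    c("A", "A", "A", "A", "A", "H", "H", "H"), # green
    c("H", "B", "B", "B", "B", "B", "B", "B")  # yellow -> causal right of M1
  )
  ph <- c("yellow", "yellow", "green", "green", "green", "green", "yellow")
  gm <- genotype_matrix(sprintf("r%d", 1:7), mk, codes, phenotype = ph)
  iv <- delimit_interval(sprintf("r%d", 1:7), gm)
  expect_identical(iv$left_marker, "M5")
  expect_identical(iv$right_marker, "M7")
  expect_identical(attr(iv, "n_used") >= 3L, TRUE)

  # intersecting fewer recombinants can only give a wider interval
  iv_sub <- delimit_interval(c("r1", "r2"), gm)
  expect_gte(iv$start, iv_sub$start)
  expect_lte(iv$end, iv_sub$end)
})

test_that("delimitation edge cases: no recombinants, conflicts", {
  mk <- data.frame(label = paste0("M", 1:3), chrom = "chr6",
                   pos = c(100, 200, 300))
  gm <- genotype_matrix(
    c("a", "b"), mk,
    rbind(c("H", "H", "H"), c("A", "A", "A")),
    phenotype = c("green", "green")
  )
  expect_warning(iv <- delimit_interval(character(0), gm), "full marker span")
  expect_identical(c(iv$left_marker, iv$right_marker), c("M1", "M3"))

  bad <- genotype_matrix(
    "x", mk, matrix(c("A", "A", "A"), 1L), phenotype = "yellow"
  )
  expect_error(delimit_interval("x", bad), "inconsistent")

  both <- genotype_matrix(
    c("x", "y"), mk,
    rbind(c("B", "B", "H"), c("H", "B", "B")), # jointly fine
    phenotype = c("yellow", "yellow")
  )
  iv2 <- delimit_interval(c("x", "y"), both)
  expect_identical(c(iv2$left_marker, iv2$right_marker), c("M1", "M3"))

  clash <- genotype_matrix(
    c("x", "y"), mk,
    rbind(c("B", "H", "H"), c("H", "H", "B")), # disjoint B segments
    phenotype = c("yellow", "yellow")
  )
  expect_error(delimit_interval(c("x", "y"), clash), "empty intersection")
})

test_that("panel concordance counts and Fisher test", {
  perfect <- simulate_panel(26L, 19L, discordant = 0L, seed = 81L)
  res <- panel_concordance(perfect)
  expect_identical(res$n_concordant, 45L)
  expect_identical(res$n_total, 45L)
  expect_true(res$perfect)
  expect_lt(res$fisher_p, 1e-10)

  # 10/0;0/10 table: exact hypergeometric enumeration gives 2 / C(20,10)
  p10 <- simulate_panel(10L, 10L, discordant = 0L, seed = 82L)
  res10 <- panel_concordance(p10)
  expect_equal(res10$fisher_p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(res10$fisher_p, 1e-4)

  # degenerate margin: single phenotype
  mono <- data.frame(id = c("a", "b"), phenotype = c("green", "green"),
                     insertion = c(FALSE, FALSE))
  expect_warning(resm <- panel_concordance(mono), "degenerate")
  expect_true(resm$perfect)
  expect_identical(resm$fisher_p, 1)
})
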