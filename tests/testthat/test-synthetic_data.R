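test_that("generators are deterministic given a seed", {
  g1 <- gen_genome(1e4, planted_sites = c(2000, 7000), seed = 5)
  g2 <- gen_genome(1e4, planted_sites = c(2000, 7000), seed = 5)
  g3 <- gen_genome(1e4, planted_sites = c(2000, 7000), seed = 6)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence, g3$sequence))

  m1 <- gen_contact_map(chrom_length = 2e5, depth = 50, seed = 2)
  m2 <- gen_contact_map(chrom_length = 2e5, depth = 50, seed = 2)
  expect_identical(m1$matrix, m2$matrix)

  e1 <- gen_chip_experiment(chrom_length = 1e4, seed = 3)
  e2 <- gen_chip_experiment(chrom_length = 1e4, seed = 3)
  expect_identical(e1$ip$values, e2$ip$values)
})

test_that("contact-map expectation follows the exponential decay", {
  # zero depth -> zero matrix
  z <- gen_contact_map(chrom_length = 1e5, depth = 0, seed = 1)
  expect_true(all(z$matrix == 0))

  # empirical decay matches exp(-s b / lambda) at high depth
  cm <- gen_contact_map(chrom_length = 1e6, bin_size = 5000,
                        lambda = 1e5, depth = 2000, seed = 8)
  N <- 200
  d <- outer(1:N, 1:N, function(i, j) pmin(abs(i - j), N - abs(i - j)))
  for (s in c(0, 5, 10, 20)) {
    emp <- mean(cm$matrix[d == s]) / 2000
    expect_equal(emp, exp(-s * 5000 / 1e5), tolerance = 0.05)
  }

  # marginals scale linearly with depth (in expectation)
  lo <- gen_contact_map(chrom_length = 2e5, depth = 100, seed = 3,
                        noise = "none")
  hi <- gen_contact_map(chrom_length = 2e5, depth = 400, seed = 3,
                        noise = "none")
  expect_equal(hi$matrix, 4 * lo$matrix, tolerance = 1e-12)
})

test_that("CID insulation attenuates exactly the cross-boundary pairs", {
  mu <- attr(gen_contact_map(chrom_length = 2e5, bin_size = 5000,
                             lambda = 1e5, depth = 100,
                             cid_boundaries = 20, insulation = 0.5,
                             seed = 1, noise = "none"), "mu")
  base <- attr(gen_contact_map(chrom_length = 2e5, bin_size = 5000,
                               lambda = 1e5, depth = 100, seed = 1,
                               noise = "none"), "mu")
  ratio <- mu / base
  # bins 20 and 21 straddle the edge; shorter arc crosses it
  expect_equal(ratio[20, 21], 0.5)
  expect_equal(ratio[15, 25], 0.5)
  expect_equal(ratio[5, 15], 1)     # same side
  expect_equal(ratio[35, 5], 1)     # shorter arc avoids the edge (wrap)
})

test_that("reduced lambda inside Ter shrinks the measured range there", {
  for (s in 1:2) {
    nm <- scn_normalize(gen_contact_map(chrom_length = 1.5e6,
                                        bin_size = 5000, lambda = 2e5,
                                        ter_interval = c(100, 200),
                                        ter_lambda_factor = 0.25,
                                        depth = 400, seed = s))
    wp <- diagonal_width_profile(significance_mask(nm))
    med_in <- summarize_range(wp, c(120, 180))$median
    med_out <- summarize_range(wp, c(230, 70))$median
    expect_lt(med_in, med_out)
  }
})

test_that("planted genomes contain exactly the planted matS sites", {
  sites <- sort(c(seq(6e5, 1.0e6, by = 5e4)))   # cluster around dif
  g <- gen_genome(2e6, planted_sites = sites, dif = 8e5, seed = 17)
  hits <- scan_motif(g$sequence)
  expect_equal(hits$position, sites)
  expect_true(all(vapply(hits$sequence, function(s)
    grepl("^GTGAC[AG][ACGT][CT]GTCAC$", s), logical(1))))
})

test_that("segment transposition performs literal string surgery", {
  # marker-word recovery: segment [100,200) -> insertion at 500
  set.seed(41)
  g <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  marker <- "TTAACCGGTTAA"
  g <- paste0(substr(g, 1, 140), marker,
              substr(g, 153, 1000))           # marker at 0-based 140
  tr <- transpose_segment(g, segment = c(100, 200),
                          insertion_point = 500)
  expect_equal(nchar(tr$sequence), 1000)
  # position 150 lifts to 450 under gap-closure coordinates
  expect_equal(tr$liftover(150), 450)
  new_pos <- tr$liftover(140)
  expect_equal(substr(tr$sequence, new_pos + 1, new_pos + 12), marker)
  expect_equal(regexpr(marker, tr$sequence, fixed = TRUE)[1] - 1, new_pos)
  # base multiset conserved
  expect_equal(sort(strsplit(tr$sequence, "")[[1]]),
               sort(strsplit(g, "")[[1]]))
})

test_that("liftover is a bijection and inverts exactly", {
  set.seed(5)
  for (rep in 1:25) {
    L <- sample(500:2000, 1)
    a <- sample(0:(L - 100), 1)
    b <- a + sample(20:90, 1)
    repeat {
      cc <- sample(0:(L - 1), 1)
      if (cc < a || cc >= b) break
    }
    inv <- runif(1) < 0.5
    tr <- transpose_segment(NULL, segment = c(a, b), insertion_point = cc,
                            inverted = inv, length = L)
    pos <- 0:(L - 1)
    fwd <- tr$liftover(pos)
    expect_equal(sort(fwd), pos)                    # bijection
    expect_equal(tr$liftover_inv(fwd), pos)         # round trip
  }
})

test_that("inverted transposition reverse-complements the segment", {
  g <- paste(rep("ACGTTGCAAC", 50), collapse = "")
  tr <- transpose_segment(g, segment = c(100, 120), insertion_point = 300,
                          inverted = TRUE)
  seg <- substr(g, 101, 120)
  seg_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seg)))
  expect_equal(substr(tr$sequence, tr$segment_new[1] + 1,
                      tr$segment_new[2]), seg_rc)
  # liftover of segment positions lands on the reinserted copy
  expect_equal(tr$liftover(100), tr$segment_new[2] - 1)
})

test_that("transposing a matS-free spacer conserves per-half site counts", {
  sites <- c(2e5, 2.5e5, 6e5, 6.5e5)
  g <- gen_genome(1e6, planted_sites = sites, seed = 23)
  # move a site-free segment [4e5, 4.5e5) to 8e5
  tr <- transpose_segment(g$sequence, segment = c(4e5, 4.5e5),
                          insertion_point = 8e5)
  hits <- scan_motif(tr$sequence)
  expect_equal(sort(hits$position), sort(tr$liftover(sites)))
  expect_equal(length(hits$position), 4)
})

test_that("synthetic ChIP tracks have the planted enrichment structure", {
  # fold 1: enrichment flat at 1 within noise
  ex1 <- gen_chip_experiment(chrom_length = 1e5, enrichment_fold = 1,
                             replicated_interval = c(0, 5e4),
                             depth = 200, seed = 31)
  enr1 <- normalize_tracks(ex1$ip, ex1$input)
  expect_equal(median(enr1$values, na.rm = TRUE), 1, tolerance = 0.05)

  # planted narrow peak recovered at the planted center
  ex2 <- gen_chip_experiment(chrom_length = 1e5,
                             peaks = data.frame(center = 40000,
                                                fold = 15, width = 50),
                             depth = 400, seed = 32)
  enr2 <- normalize_tracks(ex2$ip, ex2$input)
  pk <- call_peaks(enr2)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$center - 40000), 2)

  expect_error(gen_chip_experiment(enrichment_fold = 0.5), ">= 1")
})
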