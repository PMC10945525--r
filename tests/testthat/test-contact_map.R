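test_that("restriction digest finds cuts and tiles the chromosome", {
  # circular 20-bp toy: CCGG at 0-based 2 and 12, cut offset 1
  rm1 <- digest_genome("AACCGGTTAATTCCGGTTAA", circular = TRUE)
  expect_equal(rm1$cut_positions, c(3, 13))
  expect_equal(nrow(rm1$fragments), 2)
  expect_equal(rm1$fragments$end - rm1$fragments$start, c(10, 10))
  expect_equal(sum(rm1$fragments$end - rm1$fragments$start), 20)

  # no match on a circular genome: one fragment spanning everything
  rm2 <- digest_genome("AAAATTTTAAAATTTT", circular = TRUE)
  expect_equal(length(rm2$cut_positions), 0)
  expect_equal(rm2$fragments, data.frame(start = 0, end = 16))

  # one match on a linear sequence: two fragments
  rm3 <- digest_genome("AAAACCGGTTTT", circular = FALSE)
  expect_equal(rm3$cut_positions, 5)
  expect_equal(nrow(rm3$fragments), 2)
  expect_equal(sum(rm3$fragments$end - rm3$fragments$start), 12)

  expect_error(digest_genome(""), "empty")
  expect_error(digest_genome("ACG", site = "CCGG"), "longer")
})

test_that("fragment assignment is consistent with the tiling, incl. wrap", {
  rm1 <- digest_genome("AACCGGTTAATTCCGGTTAA", circular = TRUE)
  # fragments: [3,13) and [13,23)->wraps to 3
  expect_equal(assign_fragment(c(3, 12), rm1), c(1, 1))
  expect_equal(assign_fragment(c(13, 19, 0, 2), rm1), c(2, 2, 2, 2))
  expect_error(assign_fragment(25, rm1), "outside")
})

test_that("pair events classify into self / uncut-adjacent / valid", {
  g <- paste(rep("AACCGGTTTT", 10), collapse = "")  # cuts every 10 bp
  rmap <- digest_genome(g, circular = TRUE)
  expect_equal(nrow(rmap$fragments), 10)
  frag_pos <- function(f) rmap$fragments$start[f] %% rmap$chrom_length

  pairs <- data.frame(
    pos1    = frag_pos(c(7, 7, 7, 3, 10, 1)),
    strand1 = c("+", "+", "-", "-", "+", "-"),
    pos2    = frag_pos(c(7, 8, 8, 7, 1, 2)) + 1,
    strand2 = c("-", "-", "+", "+", "-", "-"))
  ev <- classify_events(pairs, rmap)
  expect_equal(ev$event_class,
               c("self_fragment",   # both mates fragment 7
                 "uncut_adjacent",  # 7 -> 8, inward (+,-)
                 "valid",           # 7 -> 8 but outward (-,+)
                 "valid",           # distant fragments
                 "uncut_adjacent",  # wrap adjacency 10 -> 1, inward
                 "valid"))          # adjacent but (-,-): kept
})

test_that("planted event composition is reproduced exactly", {
  g <- paste(rep("AACCGGTTTTTTTTTTTTTT", 25), collapse = "")
  rmap <- digest_genome(g, circular = TRUE)
  pairs <- gen_pair_events(rmap, n_valid = 120, n_self = 17,
                           n_uncut = 9, seed = 42)
  ev <- classify_events(pairs, rmap)
  expect_equal(sum(ev$event_class == "valid"), 120)
  expect_equal(sum(ev$event_class == "self_fragment"), 17)
  expect_equal(sum(ev$event_class == "uncut_adjacent"), 9)
})

test_that("binning counts events symmetrically with the ceiling rule", {
  # empty event list on a 10-kb chromosome
  cm0 <- bin_contacts(data.frame(pos1 = numeric(0), pos2 = numeric(0)),
                      bin_size = 5000, chrom_length = 10000)
  expect_equal(cm0$matrix, matrix(0, 2, 2))

  # events at bin pairs (1,2),(1,2),(2,2)
  ev <- data.frame(pos1 = c(100, 4000, 6000), pos2 = c(6000, 9000, 7000))
  cm <- bin_contacts(ev, bin_size = 5000, chrom_length = 10000)
  expect_equal(cm$matrix, matrix(c(0, 2, 2, 1), 2, 2))
  # total valid events = upper triangle + diagonal
  expect_equal(sum(cm$matrix[upper.tri(cm$matrix, diag = TRUE)]), 3)

  # ceiling rule: 12 kb / 5 kb -> 3 bins
  cm3 <- bin_contacts(ev, bin_size = 5000, chrom_length = 12000)
  expect_equal(nrow(cm3$matrix), 3)
  expect_error(bin_contacts(ev, bin_size = 0, chrom_length = 1e4),
               "positive")
})

test_that("SCN balancing equalizes row sums and matches a Sinkhorn oracle", {
  # constant matrix: already balanced, unchanged up to global scale
  cmc <- contact_map(matrix(4, 4, 4), 5000, 20000)
  nc <- scn_normalize(cmc)
  rs <- rowSums(nc$matrix)
  expect_equal(max(rs) - min(rs), 0, tolerance = 1e-12)
  expect_equal(nc$matrix / nc$matrix[1, 1], matrix(1, 4, 4))

  # 2x2 oracle comparison, machine precision
  M <- matrix(c(2, 1, 1, 1), 2, 2)
  nm <- scn_normalize(contact_map(M, 5000, 10000), tol = 1e-12)
  expect_equal(nm$matrix, oracle_sinkhorn(M), tolerance = 1e-9)

  # all-zero row is masked, remaining block balanced
  M3 <- matrix(c(2, 1, 0, 1, 3, 0, 0, 0, 0), 3, 3)
  n3 <- scn_normalize(contact_map(M3, 5000, 15000))
  expect_true(3 %in% n3$masked_bins)
  expect_true(all(n3$matrix[3, ] == 0) && all(n3$matrix[, 3] == 0))

  expect_error(scn_normalize(contact_map(matrix(0, 2, 2), 5000, 10000)),
               "masked")
})

test_that("SCN preserves symmetry and is idempotent", {
  nm <- small_norm_map(N = 50, seed = 7)
  expect_equal(max(abs(nm$matrix - t(nm$matrix))), 0, tolerance = 1e-12)
  again <- scn_normalize(contact_map(nm$matrix, nm$bin_size,
                                     nm$chrom_length, nm$circular,
                                     masked_bins = nm$masked_bins),
                         mask_frac = 0)
  expect_lt(max(abs(again$matrix - nm$matrix)), 1e-6)
})

test_that("log2 ratio maps follow the sign convention and smoothing oracle", {
  nm <- small_norm_map(N = 40, seed = 3)
  cm_b <- contact_map(nm$matrix, nm$bin_size, nm$chrom_length,
                      masked_bins = nm$masked_bins, state = "normalized")

  # a == b: all defined entries 0
  r0 <- log_ratio_map(cm_b, cm_b, sigma = 1)
  expect_true(all(abs(r0$matrix[!r0$undefined_mask]) < 1e-12))

  # a = 2b: +1 everywhere, invariant under smoothing
  cm_a <- contact_map(2 * nm$matrix, nm$bin_size, nm$chrom_length,
                      masked_bins = nm$masked_bins, state = "normalized")
  r2 <- log_ratio_map(cm_a, cm_b, sigma = 1)
  expect_equal(unname(r2$matrix[!r2$undefined_mask]),
               rep(1, sum(!r2$undefined_mask)), tolerance = 1e-9)

  # antisymmetry before smoothing
  rab <- log_ratio_map(cm_a, cm_b, sigma = 1)
  rba <- log_ratio_map(cm_b, cm_a, sigma = 1)
  d <- rab$unsmoothed + rba$unsmoothed
  expect_true(all(abs(d[!is.na(d)]) < 1e-12))

  expect_error(log_ratio_map(cm_a, contact_map(matrix(1, 2, 2), 5000,
                                               10000,
                                               state = "normalized")),
               "shape")
})

test_that("Gaussian impulse smoothing equals the convolution oracle", {
  m <- matrix(0, 15, 15)
  m[8, 8] <- 1
  expect_equal(gaussian_smooth_matrix(m, 1, circular = FALSE),
               oracle_gauss(m, 1, circular = FALSE), tolerance = 1e-12)
  # with NA holes and circular wrap
  m[3, 3] <- NA; m[1, 14] <- 2
  expect_equal(gaussian_smooth_matrix(m, 1, circular = TRUE),
               oracle_gauss(m, 1, circular = TRUE), tolerance = 1e-12)
})
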