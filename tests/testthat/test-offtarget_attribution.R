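toy_sites <- function() {
  data.frame(
    site_id = c("g1|c1:101:+", "g1|c1:501:+", "g1|c1:801:+"),
    guide_id = "g1", chrom = "c1",
    start = c(101L, 501L, 801L), end = c(123L, 523L, 823L),
    strand = "+", protospacer = "x", pam = "AGG", pam_class = "NGG",
    n_mismatch = c(2L, 3L, 1L), mismatch_positions = "1",
    score = 50, is_on_target = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

test_that("attribution respects the flank boundary exactly", {
  sites <- toy_sites()
  inside <- variant_frame("c1", 110L, "A", "T", sample = "e1")
  att <- attribute_variants(inside, sites, flank = 20)
  expect_equal(nrow(att$offtarget), 1L)
  expect_equal(att$offtarget$distance, 0L)

  at_edge <- variant_frame("c1", 143L, "A", "T", sample = "e1")    # end + 20
  past_edge <- variant_frame("c1", 144L, "A", "T", sample = "e1")  # end + 21
  expect_equal(nrow(attribute_variants(at_edge, sites, 20)$offtarget), 1L)
  expect_equal(attribute_variants(at_edge, sites, 20)$offtarget$distance, 20L)
  expect_equal(nrow(attribute_variants(past_edge, sites, 20)$offtarget), 0L)

  before <- variant_frame("c1", 81L, "A", "T", sample = "e1")      # start - 20
  too_far <- variant_frame("c1", 80L, "A", "T", sample = "e1")
  expect_equal(nrow(attribute_variants(before, sites, 20)$offtarget), 1L)
  expect_equal(nrow(attribute_variants(too_far, sites, 20)$offtarget), 0L)
})

test_that("deletions qualify through any deleted base; insertions via the anchor", {
  sites <- toy_sites()
  # anchor well before the flank, deleted run reaching into it
  del <- variant_frame("c1", 70L, paste0("A", strrep("T", 15)), "A",
                       sample = "e1")
  att <- attribute_variants(del, sites, flank = 20)
  expect_equal(nrow(att$offtarget), 1L)
  # insertion anchored just outside the flank stays outside
  ins <- variant_frame("c1", 80L, "A", "ATTTTTTTTTT", sample = "e1")
  expect_equal(nrow(attribute_variants(ins, sites, 20)$offtarget), 0L)
})

test_that("on-target sites are reported separately, not as off-target hits", {
  sites <- toy_sites()
  v <- variant_frame("c1", 810L, "A", "T", sample = "e1")
  att <- attribute_variants(v, sites, flank = 20)
  expect_equal(nrow(att$offtarget), 0L)
  expect_equal(nrow(att$ontarget), 1L)
  expect_identical(att$ontarget$site_id, "g1|c1:801:+")
})

test_that("attribution equals the quadratic all-pairs oracle on random data", {
  set.seed(41)
  for (rep in 1:5) {
    n_sites <- 8
    starts <- sort(sample(seq(50L, 5000L, by = 40L), n_sites))
    sites <- data.frame(
      site_id = paste0("s", seq_len(n_sites)), guide_id = "g1",
      chrom = sample(c("c1", "c2"), n_sites, replace = TRUE),
      start = starts, end = starts + 22L, strand = "+",
      protospacer = "x", pam = "AGG",
      pam_class = sample(c("NGG", "NAG", "NGA"), n_sites, replace = TRUE),
      n_mismatch = 1L, mismatch_positions = "1", score = 50,
      is_on_target = rep(c(FALSE, TRUE), c(n_sites - 1L, 1L)),
      stringsAsFactors = FALSE)
    n_var <- 40
    vars <- variant_frame(
      chrom = sample(c("c1", "c2"), n_var, replace = TRUE),
      pos = sample(5000L, n_var),
      ref = sample(c("C", "AT", "ATTT"), n_var, replace = TRUE),
      alt = "A", sample = sample(c("e1", "e2"), n_var, replace = TRUE))
    vars <- vars[vars$ref != vars$alt, ]
    flank <- sample(c(0L, 10L, 20L), 1)
    att <- attribute_variants(vars, sites, flank)$offtarget
    got <- sort(paste(att$key, att$sample, att$site_id))
    expect_identical(got, brute_force_attribution(vars, sites, flank))
  }
})

test_that("attribution grows monotonically with the flank", {
  set.seed(42)
  sites <- toy_sites()
  vars <- variant_frame("c1", sample(1000L, 60), "A", "T", sample = "e1")
  a0 <- attribute_variants(vars, sites, 0)$offtarget
  a20 <- attribute_variants(vars, sites, 20)$offtarget
  expect_true(all(paste(a0$key, a0$site_id) %in%
                    paste(a20$key, a20$site_id)))
})

test_that("a variant overlapping two sites is attributed to both, flagged ambiguous", {
  sites <- toy_sites()
  sites$start[2] <- 130L
  sites$end[2] <- 152L
  sites$site_id[2] <- "g1|c1:130:+"
  v <- variant_frame("c1", 127L, "A", "T", sample = "e1")  # within 20 of both
  att <- attribute_variants(v, sites, 20)$offtarget
  expect_equal(nrow(att), 2L)
  expect_true(all(att$ambiguous))
})

test_that("mutation ratio table reproduces the published worked examples", {
  site_counts <- data.frame(
    guide_id = c("MYB44_sg2", "ARC_sg1", "AP2_sg1", "toy"),
    pam_class = "NGG",
    n_sites = c(182L, 341L, 441L, 3L), stringsAsFactors = FALSE)
  attributed <- data.frame(
    key = c("k1", "k2", "k3", "k4", "k5"),
    sample = "e1",
    site_id = c("m1", "m2", "a1", "a1", "t1"),
    guide_id = c("MYB44_sg2", "MYB44_sg2", "ARC_sg1", "ARC_sg1", "toy"),
    pam_class = "NGG", distance = 0L, ambiguous = FALSE,
    stringsAsFactors = FALSE)
  # ARC_sg1 needs two distinct mutated sites
  attributed$site_id[4] <- "a2"
  tab <- mutation_ratio_table(attributed, site_counts)
  expect_identical(tab$label[tab$guide_id == "MYB44_sg2"], "2/182 (1.10)")
  expect_identical(tab$label[tab$guide_id == "ARC_sg1"], "2/341 (0.59)")
  expect_identical(tab$label[tab$guide_id == "AP2_sg1"], "0/441 (0.00)")
  expect_identical(tab$label[tab$guide_id == "toy"], "1/3 (33.33)")
})

test_that("ratio table drops zero denominators and rejects unknown hits", {
  site_counts <- data.frame(guide_id = "g1", pam_class = c("NGG", "NAG"),
                            n_sites = c(10L, 0L), stringsAsFactors = FALSE)
  empty_att <- data.frame(key = character(), sample = character(),
                          site_id = character(), guide_id = character(),
                          pam_class = character(), distance = integer(),
                          ambiguous = logical())
  tab <- mutation_ratio_table(empty_att, site_counts)
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$pam_class, "NGG")
  bad <- data.frame(key = "k", sample = "s", site_id = "x",
                    guide_id = "gX", pam_class = "NGG", distance = 0L,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  expect_error(mutation_ratio_table(bad, site_counts), "absent")
})

test_that("somaclonal false-attribution matches the flanked coverage fraction", {
  sim <- small_sim()
  sites <- sim$sites[!sim$sites$is_on_target, ]
  # footprint actually covered by flanked site windows, merged per chrom
  L <- sum(Biostrings::width(sim$genome))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start - 20L, sites$end + 20L)))
  covered <- sum(GenomicRanges::width(gr))
  p <- covered / L
  soma <- sim$truth[sim$truth$label %in%
                      c("somaclonal_shared", "somaclonal_private") &
                      !duplicated(sim$truth$key), ]
  vars <- variant_frame(soma$chrom, soma$pos, soma$ref, soma$alt,
                        sample = "x")
  att <- attribute_variants(vars, sim$sites, 20)$offtarget
  hit_rate <- length(unique(att$key)) / nrow(soma)
  sd3 <- 3 * sqrt(p * (1 - p) / nrow(soma))
  expect_lt(abs(hit_rate - p), sd3 + 1 / nrow(soma))
})
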