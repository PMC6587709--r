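clean_variant <- function(n = 1, sample = "s") {
  variant_frame(chrom = "c1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
                sample = sample, qual = 100, qd = 25, fs = 1, rprs = 0,
                dp = 30)
}

test_that("each hard-filter clause fires independently", {
  v <- clean_variant(6)
  v$qd[2] <- 19.9
  v$rprs[3] <- -8.1
  v$fs[4] <- 12
  v$dp[5] <- 19
  v$qual[6] <- 10   # far below the set's mean QUAL
  kept <- hard_filter(v)
  expect_identical(kept$pos, v$pos[1])

  # a single passing record survives alone
  expect_equal(nrow(hard_filter(clean_variant(1))), 1L)
})

test_that("exactly the constructed violators are removed", {
  set.seed(31)
  n <- 60
  v <- clean_variant(n)
  bad <- sample(n, 12)
  clause <- rep(c("qd", "rprs", "fs", "dp", "qual"), length.out = 12)
  for (i in seq_along(bad)) {
    j <- bad[i]
    switch(clause[i],
           qd = { v$qd[j] <- 5 },
           rprs = { v$rprs[j] <- -15 },
           fs = { v$fs[j] <- 25 },
           dp = { v$dp[j] <- 10 },
           qual = { v$qual[j] <- 20 })
  }
  kept <- hard_filter(v)
  expect_setequal(kept$pos, v$pos[-bad])
})

test_that("the mean-QUAL clause uses the pre-filter call set", {
  v <- clean_variant(4)
  v$qual <- c(100, 100, 100, 20)  # mean = 80; only the low record fails
  kept <- hard_filter(v)
  expect_equal(nrow(kept), 3L)
  # an explicit qual_min overrides the mean
  kept2 <- hard_filter(v, filter_thresholds(qual_min = 0))
  expect_equal(nrow(kept2), 4L)
})

test_that("missing annotations pass by default and fail in strict mode", {
  v <- clean_variant(2)
  v$qd[1] <- NA
  v$rprs[2] <- NA
  expect_equal(nrow(hard_filter(v)), 2L)
  expect_equal(nrow(hard_filter(v, strict_missing = TRUE)), 0L)
})

test_that("pre-existing derivation is the WT intersection", {
  expect_setequal(
    derive_preexisting(list(c("a", "b", "c"), c("a", "b"), c("a", "b", "d"))),
    c("a", "b"))
  expect_length(derive_preexisting(list(c("a"), c("b"))), 0L)
  expect_error(derive_preexisting(list(c("a"))), "at least two")
})

test_that("private derivation subtracts WT, negatives and other edited plants", {
  design <- cohort_design(
    c("w1", "w2", "n1", "e1", "e2"),
    c("WT", "WT", "NEGATIVE", "EDITED", "EDITED"),
    c("", "", "", "sg1", "sg1"))
  sets <- list(w1 = c("y"), w2 = c("y"), n1 = c("z"),
               e1 = c("x", "y", "z"), e2 = c("q"))
  r <- derive_private("e1", sets, design)
  expect_identical(r$private, "x")
  expect_setequal(r$minus_wt, c("x", "z"))
  expect_identical(r$minus_wt_ne, "x")
  # edited subset of WT leaves nothing
  sets$e1 <- c("y", "z")
  expect_length(derive_private("e1", sets, design)$private, 0L)
  expect_error(derive_private("nope", sets, design), "not in")
})

test_that("inherited keys stay private to the parent even when a sibling drops them", {
  # e1's heritable edit k is inherited by t1a and t1b; if k is missing
  # from one sibling's call set (e.g. removed by a filter), it must be
  # private to e1 only — never to a progeny sample
  design <- cohort_design(
    c("w1", "w2", "n1", "e1", "e2", "t1a", "t1b"),
    c("WT", "WT", "NEGATIVE", "EDITED", "EDITED", "EDITED", "EDITED"),
    c("", "", "", "sg1", "sg1", "sg1", "sg1"),
    c("T0", "T0", "T0", "T0", "T0", "T1", "T1"),
    c(NA, NA, NA, NA, NA, "e1", "e1"))
  sets <- list(w1 = "w", w2 = "w", n1 = "n",
               e1 = c("w", "k"), e2 = "w",
               t1a = c("w", "k", "sp1"), t1b = c("w", "sp2"))
  cs <- cohort_sets(sets, design)  # asserts pairwise disjointness
  expect_identical(cs$edited[["e1"]]$private, "k")
  expect_identical(cs$edited[["t1a"]]$private, "sp1")
  expect_identical(cs$edited[["t1b"]]$private, "sp2")
})

test_that("cohort sets recover the truth labels exactly on simulation", {
  sim <- small_sim()
  sets <- split(sim$variants$key, sim$variants$sample)
  cs <- cohort_sets(sets, sim$design)
  expect_setequal(cs$preexisting,
                  unique(sim$truth$key[sim$truth$label == "preexisting"]))
  t0_edited <- sim$design$sample_id[sim$design$role == "EDITED" &
                                      sim$design$generation == "T0"]
  for (s in t0_edited) {
    truth_private <- sim$truth$key[
      sim$truth$sample == s &
        sim$truth$label %in% c("on_target", "off_target",
                               "somaclonal_private")]
    expect_setequal(cs$edited[[s]]$private, truth_private)
  }
})

test_that("enabling the hard filters only shrinks cohort sets", {
  sim <- small_sim()
  raw_sets <- split(sim$variants$key, sim$variants$sample)
  filt_sets <- lapply(split(sim$variants, sim$variants$sample),
                      function(v) variant_key(hard_filter(v)))
  cs_raw <- cohort_sets(raw_sets, sim$design)
  cs_filt <- cohort_sets(filt_sets, sim$design)
  for (s in names(cs_filt$edited)) {
    expect_true(all(cs_filt$edited[[s]]$private %in%
                      union(cs_raw$edited[[s]]$private,
                            # removal elsewhere can only expose more keys
                            raw_sets[[s]])))
    expect_true(all(cs_filt$edited[[s]]$minus_wt %in% raw_sets[[s]]))
  }
  expect_true(all(cs_filt$preexisting %in% cs_raw$preexisting))
})

test_that("negative-overlap fractions match the truth-implied sharing", {
  sim <- small_sim()
  sets <- split(sim$variants$key, sim$variants$sample)
  ov <- overlap_fraction(sets, sim$design)
  expect_identical(ov$class, c("SNP", "indel"))
  # oracle: recompute from raw sets with plain loops
  ne <- sim$design$sample_id[sim$design$role == "NEGATIVE"]
  ed <- sim$design$sample_id[sim$design$role == "EDITED"]
  neg <- unique(unlist(sets[ne]))
  edu <- unique(unlist(sets[ed]))
  vt <- parse_variant_key(neg)$vtype
  for (cl in c("SNP", "indel")) {
    keys <- if (cl == "SNP") neg[vt == "SNP"] else neg[vt != "SNP"]
    expect_equal(ov$fraction[ov$class == cl], mean(keys %in% edu))
  }
  expect_error(overlap_fraction(list(), sim$design), "sample ids|empty")
})

test_that("toy overlap fractions behave at the boundaries", {
  design <- cohort_design(c("w1", "w2", "n1", "e1"),
                          c("WT", "WT", "NEGATIVE", "EDITED"),
                          c("", "", "", "sg1"))
  sets <- list(w1 = "c1:1:A:T", w2 = "c1:1:A:T",
               n1 = c("c1:5:A:T", "c1:9:G:C"), e1 = "c1:5:A:T")
  ov <- overlap_fraction(sets, design)
  expect_equal(ov$fraction[ov$class == "SNP"], 0.5)
  sets$e1 <- "c1:99:T:A"
  ov0 <- overlap_fraction(sets, design)
  expect_equal(ov0$fraction[ov0$class == "SNP"], 0)
})

test_that("substitution spectra are percentages that sum to 100", {
  one <- variant_frame("c1", 1L, "C", "T")
  m <- substitution_spectrum(one)
  expect_equal(m["C", "T"], 100)
  expect_equal(sum(m), 100)

  # all 12 substitution types equally often
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  v12 <- variant_frame("c1", seq_len(12) * 3L, grid$ref, grid$alt)
  m12 <- substitution_spectrum(v12)
  off_diag <- row(m12) != col(m12)
  expect_true(all(abs(m12[off_diag] - 100 / 12) < 1e-9))
  expect_true(all(m12[!off_diag] == 0))
  expect_equal(sum(m12), 100, tolerance = 1e-9)
  expect_error(substitution_spectrum(variant_frame("c1", 1L, "AT", "A")),
               "SNPs only")
})

test_that("indel lengths are tallied with type-dependent sign", {
  v <- variant_frame("c1", c(10L, 20L, 30L), c("ATTT", "A", "GC"),
                     c("A", "ACG", "G"))
  h <- indel_length_hist(v)
  expect_equal(h$count[h$vtype == "DEL" & h$length == 3], 1L)
  expect_equal(h$signed_length[h$vtype == "DEL" & h$length == 3], -3L)
  expect_equal(h$count[h$vtype == "INS" & h$length == 2], 1L)
  expect_equal(sum(h$count), 3L)
})

test_that("simulated spectra recover the transition share implied by Ts/Tv", {
  sim <- small_sim()
  snps <- sim$truth[sim$truth$vtype == "SNP" &
                      !duplicated(sim$truth$key), ]
  m <- substitution_spectrum(
    variant_frame(snps$chrom, snps$pos, snps$ref, snps$alt))
  ts <- m["A", "G"] + m["G", "A"] + m["C", "T"] + m["T", "C"]
  r <- sim$params$ts_tv_ratio
  p <- r / (r + 1)
  sd3 <- 3 * sqrt(p * (1 - p) / nrow(snps))
  expect_lt(abs(ts / 100 - p), sd3)
})
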