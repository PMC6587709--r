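test_that("an empty variant set personalizes to the identity", {
  pg0 <- planted_genome(seed = 51)
  pg <- apply_variants(pg0$genome, character(0))
  expect_identical(as.character(pg$genome), as.character(pg0$genome))
  expect_equal(map_position(pg, "chr1", c(1L, 50L, 200L)),
               c(1L, 50L, 200L))
})

test_that("a SNP substitutes in place without shifting coordinates", {
  g <- as_genome(c(chr1 = strrep("ACGT", 50)))
  pg <- apply_variants(g, variant_frame("chr1", 100L,
                                        substring(as.character(g[[1]]), 100, 100),
                                        "A") )
  expect_equal(Biostrings::width(pg$genome), Biostrings::width(g))
  expect_identical(substring(as.character(pg$genome[[1]]), 100, 100), "A")
  expect_equal(map_position(pg, "chr1", 150L), 150L)
})

test_that("deletions shift downstream coordinates and round-trip", {
  set.seed(52)
  seq <- random_seq(300)
  g <- as_genome(c(chr1 = seq))
  del <- normalize_variants(
    variant_frame("chr1", 50L, substring(seq, 50, 51), substring(seq, 50, 50)),
    g)
  pg <- apply_variants(g, del)
  dpos <- del$pos + 1L  # the deleted base
  expect_true(is.na(map_position(pg, "chr1", dpos)))
  after <- seq(dpos + 1L, 300L, by = 13L)
  expect_equal(map_position(pg, "chr1", after), as.integer(after - 1L))
  # unaffected interval round-trips exactly
  fwd <- map_position(pg, "chr1", 100:160)
  back <- map_position(pg, "chr1", fwd, direction = "personal2ref")
  expect_equal(back, 100:160)
  # direct recomputation of the personalized string
  expect_identical(as.character(pg$genome[[1]]),
                   paste0(substring(seq, 1, dpos - 1L),
                          substring(seq, dpos + 1L, 300)))
})

test_that("applying a set and its inverse round-trips the genome", {
  set.seed(53)
  seq <- random_seq(500)
  g <- as_genome(c(chr1 = seq))
  v <- variant_frame(
    "chr1", c(40L, 120L, 300L),
    c(substring(seq, 40, 40), substring(seq, 120, 122), substring(seq, 300, 300)),
    c(if (substring(seq, 40, 40) == "A") "G" else "A",
      substring(seq, 120, 120),
      paste0(substring(seq, 300, 300), "TTA")))
  pg <- apply_variants(g, v)
  nv <- pg$variants
  inv <- variant_frame(
    "chr1",
    map_position(pg, "chr1", nv$pos),
    nv$alt, nv$ref)
  back <- apply_variants(pg$genome, inv)
  expect_identical(as.character(back$genome), as.character(g))
})

test_that("conflicting variants are rejected with the offenders named", {
  g <- as_genome(c(chr1 = strrep("ACGT", 30)))
  v <- variant_frame("chr1", c(9L, 10L), c("AC", "C"), c("A", "G"))
  expect_error(apply_variants(g, v), "conflicting")
})

test_that("a WT SNP in the protospacer decrements the mismatch count", {
  pg0 <- planted_genome(seed = 54)
  # corrupt protospacer position 4 in the reference so the site carries
  # one mismatch, then let the WT variant restore the match
  seq <- as.character(pg0$genome[[1]])
  orig <- substring(seq, pg0$start + 3, pg0$start + 3)
  repl <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(seq, pg0$start + 3, pg0$start + 3) <- repl
  g <- as_genome(c(chr1 = seq))
  gd <- guide("g1", pg0$protospacer)
  sites <- enumerate_offtargets(g, gd)
  st <- sites[sites$start == pg0$start & sites$strand == "+", ]
  expect_equal(st$n_mismatch, 1L)
  wt <- variant_frame("chr1", pg0$start + 3L, repl, orig)
  re <- reassess_sites(gd, sites, wt, g)
  row <- re[re$site_id == st$site_id, ]
  expect_equal(row$mismatches_ref, 1L)
  expect_equal(row$mismatches_personal, 0L)
  expect_true(has_status(row, "mismatch_changed"))
  expect_false(has_status(row, "destroyed_site"))
})

test_that("a WT SNP turning AGG into ACG destroys the PAM and the site", {
  pg0 <- planted_genome(seed = 55)
  gd <- guide("g1", pg0$protospacer,
              loci = data.frame(chrom = "chr1", start = pg0$start,
                                strand = "+"))
  sites <- enumerate_offtargets(pg0$genome, gd)
  st <- sites[sites$start == pg0$start & sites$strand == "+", ]
  wt <- variant_frame("chr1", pg0$start + 21L, "G", "C")
  re <- reassess_sites(gd, sites, wt, pg0$genome)
  row <- re[re$site_id == st$site_id, ]
  expect_identical(row$pam_ref, "AGG")
  expect_identical(row$pam_personal, "ACG")
  expect_true(has_status(row, "pam_destroyed"))
  expect_true(has_status(row, "destroyed_site"))
  # the causal variant overlaps the site's interval
  expect_identical(row$causal_variants, variant_key(wt))
})

test_that("a WT SNP creating a PAM yields a novel site found by re-enumeration", {
  set.seed(56)
  proto <- random_seq(20)
  g <- as_genome(c(chr1 = paste0(random_seq(80), proto, "AGT",
                                 random_seq(80))))
  gd <- guide("g1", proto)
  ref_sites <- enumerate_offtargets(g, gd)
  expect_false(any(ref_sites$start == 81L & ref_sites$strand == "+"))
  wt <- variant_frame("chr1", 103L, "T", "G")  # AGT -> AGG
  re <- reassess_sites(gd, ref_sites, wt, g)
  nov <- re[has_status(re, "novel_site"), ]
  expect_equal(nrow(nov), 1L)
  expect_equal(nov$start_personal, 81L)
  expect_equal(nov$mismatches_personal, 0L)
  expect_true(has_status(nov, "pam_created"))
  expect_match(nov$causal_variants, "chr1:103:T:G", fixed = TRUE)
})

test_that("re-enumeration reports exactly the engineered novel sites", {
  set.seed(57)
  proto <- random_seq(20)
  k <- 3L
  pieces <- character(0)
  starts <- integer(0)
  pos <- 1L
  for (i in seq_len(k)) {
    gap <- random_seq(60)
    pieces <- c(pieces, gap, paste0(proto, "AGT"))
    starts <- c(starts, pos + nchar(gap))
    pos <- pos + nchar(gap) + 23L
  }
  pieces <- c(pieces, random_seq(60))
  g <- as_genome(c(chr1 = paste(pieces, collapse = "")))
  gd <- guide("g1", proto)
  ref_sites <- enumerate_offtargets(g, gd)
  wt <- variant_frame("chr1", starts + 22L, "T", "G")
  re <- reassess_sites(gd, ref_sites, wt, g)
  nov <- re[has_status(re, "novel_site"), ]
  expect_equal(nrow(nov), k)
  expect_setequal(nov$start_personal, starts)
})

test_that("the novel/PAM summary table formats n-over-total cells", {
  site_counts <- data.frame(guide_id = "g1",
                            pam_class = c("NGG", "NAG", "NGA"),
                            n_sites = c(441L, 57L, 155L),
                            stringsAsFactors = FALSE)
  re <- data.frame(
    site_id = c("novel|a", "novel|b", "novel|c", "novel|d", "x"),
    guide_id = "g1", chrom = "c1", strand = "+",
    start_ref = 1L, start_personal = 1L,
    mismatches_ref = 5L, mismatches_personal = 4L,
    pam_ref = c(NA, NA, NA, NA, "AGG"),
    pam_personal = c("AGG", "TGG", "CGG", "GGG", "ACG"),
    status = c(rep("novel_site", 4), "pam_destroyed;destroyed_site"),
    causal_variants = "c1:1:A:T", stringsAsFactors = FALSE)
  tab <- novel_site_table(re, site_counts)
  expect_identical(tab$label[tab$pam_class == "NGG" & tab$level == "site"],
                   "4/441")
  expect_identical(tab$label[tab$pam_class == "NGG" & tab$level == "pam"],
                   "1/441")
  expect_identical(tab$label[tab$pam_class == "NAG" & tab$level == "site"],
                   "0/57")
  expect_equal(sum(tab$n), 5L)
})

test_that("reassessment is empty when the WT carries no variants near sites", {
  pg0 <- planted_genome(seed = 58)
  gd <- guide("g1", pg0$protospacer)
  sites <- enumerate_offtargets(pg0$genome, gd)
  re <- reassess_sites(gd, sites,
                       variant_frame(character(0), integer(0),
                                     character(0), character(0)),
                       pg0$genome)
  expect_equal(nrow(re), 0L)
})
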