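# Shared fixtures and independent oracles. Everything here is written
# deliberately naively (plain loops, explicit string comparison) so the
# tests cross-check the vectorized implementation against a second,
# simpler route.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

# naive position-by-position scan of both strands; the oracle for the
# enumerator's contract
brute_force_sites <- function(genome, protospacer, max_mm,
                              pam_classes = c("NGG", "NAG", "NGA")) {
  gchars <- strsplit(protospacer, "")[[1]]
  rows <- list()
  for (chrom in names(genome)) {
    seq_fwd <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    L <- length(seq_fwd)
    if (L < 23) next
    for (strand in c("+", "-")) {
      chars <- if (strand == "+") seq_fwd else rc_chars(seq_fwd)
      for (i in seq_len(L - 22)) {
        win <- chars[i:(i + 22)]
        if (any(win == "N")) next
        p23 <- win[21:23]
        cls <- if (p23[2] == "G" && p23[3] == "G") "NGG"
        else if (p23[2] == "A" && p23[3] == "G") "NAG"
        else if (p23[2] == "G" && p23[3] == "A") "NGA"
        else "none"
        if (!cls %in% pam_classes) next
        mm <- sum(win[1:20] != gchars)
        if (mm > max_mm) next
        start <- if (strand == "+") i else L - i - 21
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = start, strand = strand,
          n_mismatch = mm, pam_class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), n_mismatch = integer(),
                      pam_class = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

site_signature <- function(df) {
  sort(paste(df$chrom, df$start, df$strand, df$n_mismatch, df$pam_class))
}

# quadratic all-pairs interval check; the oracle for flank attribution
brute_force_attribution <- function(variants, sites, flank) {
  pairs <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    lr <- nchar(v$ref)
    vs <- if (v$vtype == "DEL") v$pos + 1 else v$pos
    ve <- if (v$vtype %in% c("DEL", "MNP")) v$pos + lr - 1 else vs
    ve <- max(vs, ve)
    for (j in seq_len(nrow(sites))) {
      s <- sites[j, ]
      if (s$is_on_target) next
      if (v$chrom == s$chrom && vs <= s$end + flank && ve >= s$start - flank) {
        pairs <- c(pairs, paste(variant_key(v), v$sample, s$site_id))
      }
    }
  }
  sort(pairs)
}

# fast small-scale study used by several files; cached per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_params(
        genome_length = 60000L, n_preexisting = 60L,
        n_somaclonal_shared = 20L, n_somaclonal_private = 15L,
        n_spontaneous_T1 = 10L, seed = 7L))
    }
    cache
  }
})

# a tiny constructed genome holding one exact guide site, for the
# personalization tests
planted_genome <- function(protospacer = "ACGTTGCAGGATCCGTTAAC",
                           pam = "AGG", left = 100, right = 100,
                           seed = 5) {
  set.seed(seed)
  lseq <- random_seq(left)
  rseq <- random_seq(right)
  list(genome = as_genome(c(chr1 = paste0(lseq, protospacer, pam, rseq))),
       start = left + 1, protospacer = protospacer)
}
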