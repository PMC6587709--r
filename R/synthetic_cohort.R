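#' Simulation parameters for a synthetic edited-plant cohort
#'
#' Defaults describe the desk-scale study conditions the package is
#' exercised under: a two-chromosome 200-kb genome standing in for the
#' At/Dt subgenome pair, a cohort of 3 wild-type, 3 negative
#' (tissue-culture-only) and 4 Cas9-edited T0 plants plus 2 T1 progeny
#' of the first edited plant, deletion-dominant edit types, and an
#' off-target edit probability decaying logistically in the mismatch
#' count. See the methods vignette for the rationale behind each value.
#'
#' @param genome_length total genome length in bp (>= 1000).
#' @param n_chroms number of chromosomes.
#' @param gc_fraction genome GC content in (0, 1).
#' @param n_wt,n_negative,n_edited,n_t1 cohort composition.
#' @param n_preexisting maternal variants shared by every sample.
#' @param n_somaclonal_shared target mean number of shared somaclonal
#'   variants per regenerant (drawn from a common pool, each pool variant
#'   assigned to at least two regenerants).
#' @param n_somaclonal_private unique somaclonal variants per regenerant.
#' @param on_target_efficiency probability an intended locus is edited in
#'   an edited plant.
#' @param edit_type_weights sampling weights over edit types d1/d2/d3/i1/s.
#' @param offtarget_edit_prob function(mismatch count) -> edit probability
#'   per site per edited plant.
#' @param n_spontaneous_T1 new spontaneous mutations per T1 plant.
#' @param background_snp_fraction SNP share of non-edit variants.
#' @param ts_tv_ratio transition/transversion ratio for simulated SNPs.
#' @param fail_filter_fraction fraction of each sample's records given
#'   annotations that violate exactly one hard-filter clause.
#' @param seed integer seed; every simulator entry point derives its RNG
#'   stream from it.
#' @return validated `sim_params` list.
#' @export
sim_params <- function(genome_length = 200000L,
                       n_chroms = 2L,
                       gc_fraction = 0.35,
                       n_wt = 3L, n_negative = 3L, n_edited = 4L, n_t1 = 2L,
                       n_preexisting = 200L,
                       n_somaclonal_shared = 60L,
                       n_somaclonal_private = 40L,
                       on_target_efficiency = 0.85,
                       edit_type_weights = c(d1 = 0.40, d2 = 0.20, d3 = 0.05,
                                             i1 = 0.20, s = 0.15),
                       offtarget_edit_prob = function(mm)
                         0.3 * stats::plogis(1.5 * (1 - mm)),
                       n_spontaneous_T1 = 30L,
                       background_snp_fraction = 0.9,
                       ts_tv_ratio = 2,
                       fail_filter_fraction = 0.05,
                       seed = 1L) {
  p <- list(genome_length = as.integer(genome_length),
            n_chroms = as.integer(n_chroms), gc_fraction = gc_fraction,
            n_wt = as.integer(n_wt), n_negative = as.integer(n_negative),
            n_edited = as.integer(n_edited), n_t1 = as.integer(n_t1),
            n_preexisting = as.integer(n_preexisting),
            n_somaclonal_shared = as.integer(n_somaclonal_shared),
            n_somaclonal_private = as.integer(n_somaclonal_private),
            on_target_efficiency = on_target_efficiency,
            edit_type_weights = edit_type_weights,
            offtarget_edit_prob = offtarget_edit_prob,
            n_spontaneous_T1 = as.integer(n_spontaneous_T1),
            background_snp_fraction = background_snp_fraction,
            ts_tv_ratio = ts_tv_ratio,
            fail_filter_fraction = fail_filter_fraction,
            seed = as.integer(seed))
  counts <- c(p$genome_length, p$n_chroms, p$n_wt, p$n_negative, p$n_edited,
              p$n_t1, p$n_preexisting, p$n_somaclonal_shared,
              p$n_somaclonal_private, p$n_spontaneous_T1)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (p$genome_length < 1000L) stop("genome_length must be >= 1000")
  if (p$gc_fraction <= 0 || p$gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  probs <- c(p$on_target_efficiency, p$background_snp_fraction,
             p$fail_filter_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!setequal(names(p$edit_type_weights), c("d1", "d2", "d3", "i1", "s"))) {
    stop("edit_type_weights needs names d1, d2, d3, i1, s")
  }
  if (abs(sum(p$edit_type_weights) - 1) > 1e-8) {
    stop("edit_type_weights must sum to 1")
  }
  if (!is.function(p$offtarget_edit_prob)) {
    stop("offtarget_edit_prob must be a function of the mismatch count")
  }
  structure(p, class = "sim_params")
}

#' Generate an i.i.d. random genome
#'
#' Bases drawn independently with the stated GC fraction; deterministic
#' under `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return a genome (`DNAStringSet`) with chromosomes chr1..chrN.
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  gc <- params$gc_fraction
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  len <- rep(params$genome_length %/% params$n_chroms, params$n_chroms)
  len[1L] <- len[1L] + params$genome_length %% params$n_chroms
  seqs <- vapply(len, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(params$n_chroms))
  as_genome(seqs)
}

resolve_pam <- function(pattern, class = NULL) {
  # concrete 3-mer for a pattern such as NGG; the leading N becomes A
  if (!is.null(class)) pattern <- class
  chartr("N", "A", toupper(pattern))
}

#' Implant exact target loci and mismatch decoys into a genome
#'
#' Exact loci receive the guide's protospacer+PAM verbatim (the PAM
#' pattern's N resolved to A); each decoy receives a copy of the
#' protospacer altered at exactly `k_mismatch` random positions plus a
#' PAM of the requested class. Minus-strand implants are
#' reverse-complemented. Uses the session RNG (seed upstream for
#' reproducibility).
#'
#' @param genome genome to modify.
#' @param guide one-row guide table (see [guide()]).
#' @param exact_loci data.frame (chrom, start, strand) of 23-bp windows.
#' @param decoys data.frame (chrom, start, strand, k_mismatch, pam_class);
#'   may have zero rows.
#' @return the modified genome.
#' @export
implant_target_loci <- function(genome, guide, exact_loci,
                                decoys = data.frame()) {
  genome <- as_genome(genome)
  validate_guides(guide)
  if (nrow(decoys) == 0L) {
    decoys <- data.frame(chrom = character(), start = integer(),
                         strand = character(), k_mismatch = integer(),
                         pam_class = character())
  }
  if (any(decoys$k_mismatch < 0L | decoys$k_mismatch > 6L)) {
    stop("k_mismatch must lie in 0..6")
  }
  all_loci <- rbind(exact_loci[, c("chrom", "start", "strand")],
                    decoys[, c("chrom", "start", "strand")])
  chrom_seq <- as.character(genome)
  ends <- all_loci$start + 22L
  for (i in seq_len(nrow(all_loci))) {
    L <- nchar(chrom_seq[[all_loci$chrom[i]]])
    if (all_loci$start[i] < 1L || ends[i] > L) {
      stop("locus out of range on ", all_loci$chrom[i])
    }
  }
  ir <- split(IRanges::IRanges(all_loci$start, ends), all_loci$chrom)
  for (ch in names(ir)) {
    if (any(IRanges::countOverlaps(ir[[ch]], ir[[ch]]) > 1L)) {
      stop("implanted loci overlap on ", ch)
    }
  }
  proto <- guide$protospacer[1L]
  write_site <- function(chrom, start, strand, seq23) {
    if (strand == "-") seq23 <- revcomp(seq23)
    s <- chrom_seq[[chrom]]
    substr(s, start, start + 22L) <- seq23
    chrom_seq[[chrom]] <<- s
  }
  for (i in seq_len(nrow(exact_loci))) {
    write_site(exact_loci$chrom[i], exact_loci$start[i],
               exact_loci$strand[i],
               paste0(proto, resolve_pam(guide$pam[1L])))
  }
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(decoys))) {
    k <- decoys$k_mismatch[i]
    chars <- strsplit(proto, "", fixed = TRUE)[[1]]
    if (k > 0L) {
      at <- sample(20L, k)
      for (j in at) chars[j] <- sample(setdiff(bases, chars[j]), 1L)
    }
    pam <- paste0(sample(bases, 1L),
                  substring(decoys$pam_class[i], 2L, 3L))
    write_site(decoys$chrom[i], decoys$start[i], decoys$strand[i],
               paste0(paste(chars, collapse = ""), pam))
  }
  as_genome(chrom_seq)
}

## ---- variant fabrication helpers --------------------------------------

new_interval_set <- function() new.env(parent = emptyenv())

iv_overlaps <- function(env, chrom, start, end) {
  iv <- env[[chrom]]
  if (is.null(iv)) return(FALSE)
  any(iv[, 1L] <= end & iv[, 2L] >= start)
}

iv_add <- function(env, chrom, start, end) {
  env[[chrom]] <- rbind(env[[chrom]], c(start, end))
}

random_snp_alt <- function(ref, ts_tv_ratio) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < ts_tv_ratio / (ts_tv_ratio + 1)) {
    transition[[ref]]
  } else {
    sample(setdiff(c("A", "C", "G", "T"), c(ref, transition[[ref]])), 1L)
  }
}

# fabricate one background variant (SNP-dominant mix), normalized, at a
# position free of `occ` intervals and `excl` windows; returns a one-row
# variant df or NULL after too many rejections
fabricate_background <- function(chrom_seq, occ, excl, params) {
  bases <- c("A", "C", "G", "T")
  lens <- nchar(chrom_seq)
  for (try in 1:200) {
    chrom <- sample(names(chrom_seq), 1L, prob = lens)
    L <- lens[[chrom]]
    pos <- sample(seq(10L, L - 10L), 1L)
    if (stats::runif(1) < params$background_snp_fraction) {
      ref <- substring(chrom_seq[[chrom]], pos, pos)
      if (!ref %in% bases) next
      alt <- random_snp_alt(ref, params$ts_tv_ratio)
      span <- c(pos, pos)
    } else {
      k <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      if (stats::runif(1) < 0.5) {  # deletion
        ref <- substring(chrom_seq[[chrom]], pos, pos + k)
        alt <- substring(ref, 1L, 1L)
      } else {                      # insertion
        ref <- substring(chrom_seq[[chrom]], pos, pos)
        alt <- paste0(ref, paste(sample(bases, k, replace = TRUE),
                                 collapse = ""))
      }
      if (grepl("[^ACGT]", ref)) next
      span <- c(pos, pos + nchar(ref) - 1L)
    }
    v <- variant_frame(chrom, pos, ref, alt)
    v <- norm1(v, chrom_seq[[chrom]])
    span <- c(min(span[1L], v$pos), max(span[2L], v$pos + nchar(v$ref) - 1L))
    # keep a 1-bp guard band so neighbouring indels stay conflict-free
    if (iv_overlaps(occ, chrom, span[1L] - 1L, span[2L] + 1L)) next
    if (iv_overlaps(excl, chrom, span[1L], span[2L])) next
    iv_add(occ, chrom, span[1L], span[2L])
    v$vtype <- variant_type(v$ref, v$alt)
    return(v)
  }
  NULL
}

# fabricate a Cas9-style edit inside a site's 23-bp window, near the
# cleavage position (3 bp from the PAM); key must be globally unique
fabricate_edit <- function(site, chrom_seq, used_keys, params) {
  bases <- c("A", "C", "G", "T")
  types <- names(params$edit_type_weights)
  for (try in 1:60) {
    type <- sample(types, 1L, prob = params$edit_type_weights)
    anchor_lo <- if (site$strand == "+") site$start + 10L else site$start + 3L
    anchor <- anchor_lo + sample(0:6, 1L)
    k <- if (type == "i1") 1L else as.integer(substring(type, 2L))
    if (type == "s") {
      ref <- substring(chrom_seq[[site$chrom]], anchor, anchor)
      if (!ref %in% bases) next
      alt <- random_snp_alt(ref, params$ts_tv_ratio)
    } else if (type == "i1") {
      ref <- substring(chrom_seq[[site$chrom]], anchor, anchor)
      if (!ref %in% bases) next
      alt <- paste0(ref, sample(bases, 1L))
    } else {
      ref <- substring(chrom_seq[[site$chrom]], anchor, anchor + k)
      if (grepl("[^ACGT]", ref)) next
      if (anchor + k > site$end) next
      alt <- substring(ref, 1L, 1L)
    }
    v <- variant_frame(site$chrom, anchor, ref, alt)
    v <- norm1(v, chrom_seq[[site$chrom]])
    v$vtype <- variant_type(v$ref, v$alt)
    # left-alignment must not carry the edit outside its site
    if (v$pos < site$start || v$pos + nchar(v$ref) - 1L > site$end) next
    if (variant_key(v) %in% used_keys) next
    return(v)
  }
  NULL
}

draw_annotations <- function(n, params) {
  fails <- stats::runif(n) < params$fail_filter_fraction
  clause <- rep(NA_character_, n)
  clause[fails] <- sample(c("QD", "FS", "ReadPosRankSum", "QUAL", "DP"),
                          sum(fails), replace = TRUE)
  df <- data.frame(
    qual = rep(100, n),
    qd = 25 + abs(stats::rnorm(n, 0, 3)),
    fs = stats::runif(n, 0, 5),
    rprs = pmax(-4, pmin(4, stats::rnorm(n))),
    dp = 20 + stats::rpois(n, 15),
    gt = sample(c("0/1", "1/1"), n, replace = TRUE, prob = c(0.7, 0.3)),
    fails_filter = fails, fail_clause = clause,
    stringsAsFactors = FALSE
  )
  df$qd[which(clause == "QD")] <- stats::runif(sum(clause == "QD", na.rm = TRUE), 5, 15)
  df$fs[which(clause == "FS")] <- stats::runif(sum(clause == "FS", na.rm = TRUE), 11, 30)
  df$rprs[which(clause == "ReadPosRankSum")] <-
    stats::runif(sum(clause == "ReadPosRankSum", na.rm = TRUE), -20, -9)
  df$qual[which(clause == "QUAL")] <- 20
  df$dp[which(clause == "DP")] <- sample(5:19, sum(clause == "DP", na.rm = TRUE),
                                         replace = TRUE)
  df
}

## ---- cohort simulation -------------------------------------------------

#' Simulate per-sample variant sets with truth labels
#'
#' Given a genome with implanted target loci and decoys, generates the
#' cohort's variant sets with the causal structure the pipeline's
#' inference assumes: pre-existing variants identical in every sample;
#' shared somaclonal variants drawn from a pool (each in at least two
#' regenerants); private somaclonal variants unique per regenerant;
#' on-target edits at intended loci with the stated efficiency and
#' deletion-dominant type mix; off-target edits at enumerated sites with
#' probability `offtarget_edit_prob(mismatch count)`, placed inside the
#' 23-bp site; T1 samples inherit all parent variants plus new
#' spontaneous mutations (placed away from any site so cross-generation
#' isolation is exact). Caller annotations are drawn so that a
#' configurable fraction of records violates exactly one hard-filter
#' clause; the truth table records which.
#'
#' @param genome genome with loci already implanted (see
#'   [implant_target_loci()]).
#' @param guides guide table with intended loci recorded.
#' @param design cohort design table.
#' @param params a [sim_params()] object.
#' @return list: `variants` (all samples stacked, with annotations),
#'   `truth` (sample, key, label, site_id, fails_filter, fail_clause),
#'   `sites` (the enumeration used), `design`, `params`.
#' @export
simulate_cohort <- function(genome, guides, design, params) {
  stopifnot(inherits(params, "sim_params"))
  genome <- as_genome(genome)
  validate_design(design)
  validate_guides(guides)
  edited <- design$sample_id[design$role == "EDITED" &
                               design$generation == "T0"]
  for (s in edited) {
    for (g in design_guides(design, s)) {
      if (nrow(guide_loci(guides, g)) == 0L) {
        stop("edited sample ", s, " uses guide ", g, " with no implanted loci")
      }
    }
  }
  set.seed(params$seed + 1L)
  chrom_seq <- as.character(genome)
  sites <- enumerate_offtargets(genome, guides)
  occ <- new_interval_set()
  excl <- new_interval_set()
  on_sites <- sites[sites$is_on_target, , drop = FALSE]
  for (i in seq_len(nrow(on_sites))) {
    iv_add(excl, on_sites$chrom[i], on_sites$start[i], on_sites$end[i])
  }
  spont_excl <- new_interval_set()
  for (i in seq_len(nrow(sites))) {
    iv_add(spont_excl, sites$chrom[i], sites$start[i] - 20L,
           sites$end[i] + 20L)
  }

  regen <- design$sample_id[design$generation == "T0" &
                              design$role %in% c("NEGATIVE", "EDITED")]
  t0 <- design$sample_id[design$generation == "T0"]
  t1 <- design$sample_id[design$generation == "T1"]

  per_sample <- setNames(vector("list", nrow(design)), design$sample_id)
  add_var <- function(sample, v, label, site_id = NA_character_) {
    v$sample <- sample
    v$label <- label
    v$site_id <- site_id
    per_sample[[sample]] <<- c(per_sample[[sample]], list(v))
  }

  # pre-existing: identical in every T0 sample
  for (i in seq_len(params$n_preexisting)) {
    v <- fabricate_background(chrom_seq, occ, excl, params)
    if (is.null(v)) stop("could not place pre-existing variant")
    for (s in t0) add_var(s, v, "preexisting")
  }

  # shared somaclonal pool: each pool variant lands in >= 2 regenerants
  if (length(regen) >= 2L && params$n_somaclonal_shared > 0L) {
    mean_mult <- 2 + 0.3 * max(0L, length(regen) - 2L)
    pool_n <- max(1L, round(length(regen) * params$n_somaclonal_shared /
                              mean_mult))
    for (i in seq_len(pool_n)) {
      v <- fabricate_background(chrom_seq, occ, excl, params)
      if (is.null(v)) stop("could not place shared somaclonal variant")
      mult <- 2L + stats::rbinom(1L, length(regen) - 2L, 0.3)
      for (s in sample(regen, mult)) add_var(s, v, "somaclonal_shared")
    }
  }

  # private somaclonal variants, unique per regenerant
  for (s in regen) {
    for (i in seq_len(params$n_somaclonal_private)) {
      v <- fabricate_background(chrom_seq, occ, excl, params)
      if (is.null(v)) stop("could not place private somaclonal variant")
      add_var(s, v, "somaclonal_private")
    }
  }

  used_keys <- unique(unlist(lapply(per_sample, function(l)
    vapply(l, variant_key, character(1))), use.names = FALSE))

  # Cas9 edits in edited T0 samples
  ed_sites_of <- function(s) {
    gids <- design_guides(design, s)
    sites[sites$guide_id %in% gids, , drop = FALSE]
  }
  for (s in edited) {
    ss <- ed_sites_of(s)
    ons <- ss[ss$is_on_target, , drop = FALSE]
    offs <- ss[!ss$is_on_target, , drop = FALSE]
    for (i in seq_len(nrow(ons))) {
      if (stats::runif(1) > params$on_target_efficiency) next
      v <- fabricate_edit(ons[i, ], chrom_seq, used_keys, params)
      if (is.null(v)) next
      used_keys <- c(used_keys, variant_key(v))
      add_var(s, v, "on_target", ons$site_id[i])
    }
    if (nrow(offs) > 0L) {
      p <- params$offtarget_edit_prob(offs$n_mismatch)
      hit <- stats::runif(nrow(offs)) < p
      for (i in which(hit)) {
        v <- fabricate_edit(offs[i, ], chrom_seq, used_keys, params)
        if (is.null(v)) next
        used_keys <- c(used_keys, variant_key(v))
        add_var(s, v, "off_target", offs$site_id[i])
      }
    }
  }

  # T1: inherit the parent wholesale, then add spontaneous mutations
  for (s in t1) {
    parent <- design$parent_id[design$sample_id == s]
    for (v in per_sample[[parent]]) {
      w <- v
      add_var(s, w[, setdiff(names(w), c("sample", "label", "site_id"))],
              v$label[1L], v$site_id[1L])
    }
    for (i in seq_len(params$n_spontaneous_T1)) {
      v <- fabricate_background(chrom_seq, occ, spont_excl, params)
      if (is.null(v)) stop("could not place spontaneous variant")
      add_var(s, v, "spontaneous")
    }
  }

  # assemble + annotate
  all_rows <- list()
  for (s in design$sample_id) {
    lst <- per_sample[[s]]
    if (length(lst) == 0L) next
    df <- do.call(rbind, lst)
    ann <- draw_annotations(nrow(df), params)
    df$qual <- ann$qual; df$qd <- ann$qd; df$fs <- ann$fs
    df$rprs <- ann$rprs; df$dp <- ann$dp; df$gt <- ann$gt
    df$fails_filter <- ann$fails_filter
    df$fail_clause <- ann$fail_clause
    all_rows[[s]] <- df
  }
  variants <- do.call(rbind, all_rows)
  rownames(variants) <- NULL
  variants$key <- variant_key(variants)
  truth <- variants[, c("sample", "key", "chrom", "pos", "ref", "alt",
                        "vtype", "label", "site_id", "fails_filter",
                        "fail_clause")]
  # truth labels partition each sample's set
  stopifnot(!anyDuplicated(paste(truth$sample, truth$key)))
  out_cols <- c(variant_columns, "key")
  list(variants = variants[, out_cols], truth = truth, sites = sites,
       design = design, params = params)
}

#' Default cohort design matching the simulator's study conditions
#'
#' @param params a [sim_params()] object.
#' @param guide_ids guide ids to distribute round-robin over the edited
#'   samples.
#' @return cohort design table (WT / negative / edited T0 plants, plus T1
#'   progeny of the first edited plant).
#' @export
default_cohort_design <- function(params = sim_params(),
                                  guide_ids = c("sg1", "sg2")) {
  ids <- c(paste0("WT", seq_len(params$n_wt)),
           paste0("Ne", seq_len(params$n_negative)),
           paste0("Ed", seq_len(params$n_edited)))
  roles <- c(rep("WT", params$n_wt), rep("NEGATIVE", params$n_negative),
             rep("EDITED", params$n_edited))
  gids <- c(rep("", params$n_wt + params$n_negative),
            rep_len(guide_ids, params$n_edited))
  gen <- rep("T0", length(ids))
  parent <- rep(NA_character_, length(ids))
  if (params$n_t1 > 0L) {
    if (params$n_edited < 1L) stop("T1 progeny need an edited T0 parent")
    ids <- c(ids, paste0("T1_", seq_len(params$n_t1)))
    roles <- c(roles, rep("EDITED", params$n_t1))
    gids <- c(gids, rep(gids[params$n_wt + params$n_negative + 1L],
                        params$n_t1))
    gen <- c(gen, rep("T1", params$n_t1))
    parent <- c(parent, rep("Ed1", params$n_t1))
  }
  cohort_design(ids, roles, gids, gen, parent)
}

#' One-call synthetic study
#'
#' Generates the genome, two guides with subgenome-style duplicated or
#' single intended loci, a ladder of mismatch decoys per guide, implants
#' everything, and simulates the cohort. Optionally writes the whole
#' study (FASTA, per-sample VCFs, guide/design TSVs, site table, truth
#' JSON) to a directory.
#'
#' @param params a [sim_params()] object.
#' @param out_dir optional output directory.
#' @return the [simulate_cohort()] result plus `genome`, `guides` and
#'   `decoys`.
#' @export
simulate_study <- function(params = sim_params(), out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  genome <- generate_genome(params)
  set.seed(params$seed + 2L)
  chroms <- names(genome)
  lens <- Biostrings::width(genome)

  proto <- replicate(2, {
    repeat {
      p <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                 collapse = "")
      if (gc_content(p) >= 0.4 && gc_content(p) <= 0.6) break
    }
    p
  })
  # guide 1: duplicated loci on the two "subgenome" chromosomes;
  # guide 2: single locus
  loci1 <- data.frame(chrom = chroms[c(1L, min(2L, length(chroms)))],
                      start = as.integer(round(lens[c(1L, min(2L, length(chroms)))] * 0.25)),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  if (length(chroms) == 1L) loci1 <- loci1[1L, , drop = FALSE]
  loci2 <- data.frame(chrom = chroms[1L],
                      start = as.integer(round(lens[1L] * 0.6)),
                      strand = "-", stringsAsFactors = FALSE)
  guides <- rbind(guide("sg1", proto[1L], gene = "geneA", loci = loci1),
                  guide("sg2", proto[2L], gene = "geneB", loci = loci2))

  reserved <- IRanges::IRanges()
  res_chrom <- character(0)
  reserve <- function(chrom, start) {
    reserved <<- c(reserved, IRanges::IRanges(start - 30L, start + 52L))
    res_chrom <<- c(res_chrom, chrom)
  }
  for (df in list(loci1, loci2)) {
    for (i in seq_len(nrow(df))) reserve(df$chrom[i], df$start[i])
  }
  place <- function() {
    repeat {
      chrom <- sample(chroms, 1L, prob = lens)
      L <- lens[[match(chrom, chroms)]]
      start <- sample(seq(100L, L - 130L), 1L)
      probe <- IRanges::IRanges(start, start + 22L)
      same <- res_chrom == chrom
      if (!any(IRanges::overlapsAny(probe, reserved[same]))) {
        reserve(chrom, start)
        return(c(chrom, start))
      }
    }
  }
  decoy_plan <- data.frame(
    k_mismatch = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L),
    pam_class = c("NGG", "NAG", "NGA", "NGG", "NAG", "NGG", "NGA", "NGG", "NGG"),
    stringsAsFactors = FALSE
  )
  decoys <- list()
  for (g in guides$id) {
    d <- decoy_plan
    d$guide_id <- g
    pos <- t(vapply(seq_len(nrow(d)), function(i) place(), character(2)))
    d$chrom <- pos[, 1L]
    d$start <- as.integer(pos[, 2L])
    d$strand <- sample(c("+", "-"), nrow(d), replace = TRUE)
    decoys[[g]] <- d
  }
  decoys <- do.call(rbind, decoys)
  rownames(decoys) <- NULL

  for (g in guides$id) {
    genome <- implant_target_loci(genome, guides[guides$id == g, ],
                                  guide_loci(guides, g),
                                  decoys[decoys$guide_id == g, ])
  }
  design <- default_cohort_design(params, guides$id)
  sim <- simulate_cohort(genome, guides, design, params)
  sim$genome <- genome
  sim$guides <- guides
  sim$decoys <- decoys
  if (!is.null(out_dir)) write_study(sim, out_dir)
  sim
}

#' Write a simulated study to disk
#'
#' Emits genome.fasta, guides.tsv, design.tsv, sites.tsv, sites.bed,
#' one `<sample>.vcf` per sample, and truth.json.
#'
#' @param sim result of [simulate_study()] (or [simulate_cohort()] with a
#'   `genome` element added).
#' @param out_dir directory (created if needed).
#' @export
write_study <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(out_dir, "genome.fasta"))
  write_guides(sim$guides, file.path(out_dir, "guides.tsv"))
  write_cohort_design(sim$design, file.path(out_dir, "design.tsv"))
  write.table(sim$sites, file.path(out_dir, "sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_sites_bed(sim$sites, file.path(out_dir, "sites.bed"))
  for (s in unique(sim$variants$sample)) {
    write_vcf(sim$variants[sim$variants$sample == s, ],
              file.path(out_dir, paste0(s, ".vcf")))
  }
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(out_dir)
}
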