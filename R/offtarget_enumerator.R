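#' Classify a PAM triplet
#'
#' Class is determined by positions 2–3 of the 3-mer: GG -> NGG,
#' AG -> NAG, GA -> NGA; anything else (including N at positions 2–3) is
#' "none". The leading base is the N of the motif and never constrains
#' the class.
#'
#' @param triplet character vector of 3-mers over A/C/G/T/N.
#' @return character vector in `{NGG, NAG, NGA, none}`.
#' @export
classify_pam <- function(triplet) {
  triplet <- toupper(triplet)
  if (any(nchar(triplet) != 3L)) stop("PAM must be a 3-mer")
  tail2 <- substring(triplet, 2L, 3L)
  out <- rep("none", length(triplet))
  out[tail2 == "GG"] <- "NGG"
  out[tail2 == "AG"] <- "NAG"
  out[tail2 == "GA"] <- "NGA"
  out
}

empty_sites <- function() {
  data.frame(site_id = character(), guide_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), protospacer = character(),
             pam = character(), pam_class = character(),
             n_mismatch = integer(), mismatch_positions = character(),
             score = numeric(), is_on_target = logical(),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate off-target sites genome-wide
#'
#' Reports every 23-bp window, on either strand, whose trailing 3-mer
#' classifies into one of the requested PAM classes and whose leading
#' 20-mer mismatches the guide's protospacer at no more than
#' `max_mismatches` positions. Minus-strand hits are reported in
#' plus-strand coordinates (1-based closed interval of width 23) with
#' `strand = "-"`. Windows containing N are excluded, as are incomplete
#' windows at chromosome edges. Intended loci of the guide are flagged
#' `is_on_target`. Sites carry the [specificity_score()] and mismatch
#' positions indexed with 1 = PAM-distal.
#'
#' @param genome a genome object.
#' @param guides guide table (see [guide()]); all guides are enumerated.
#' @param max_mismatches protospacer mismatch budget (default 5).
#' @param pam_classes subset of NGG/NAG/NGA to admit.
#' @param model score model for [specificity_score()].
#' @return site data.frame sorted by (guide, chrom, start, strand).
#' @export
enumerate_offtargets <- function(genome, guides, max_mismatches = 5L,
                                 pam_classes = c("NGG", "NAG", "NGA"),
                                 model = score_model()) {
  genome <- as_genome(genome)
  stopifnot(max_mismatches >= 0L, max_mismatches <= 20L)
  pam_classes <- match.arg(pam_classes, c("NGG", "NAG", "NGA"),
                           several.ok = TRUE)
  validate_guides(guides)
  out <- list()
  chrom_seq <- as.character(genome)
  for (gi in seq_len(nrow(guides))) {
    gid <- guides$id[gi]
    proto <- guides$protospacer[gi]
    proto_chars <- strsplit(proto, "", fixed = TRUE)[[1]]
    loci <- guide_loci(guides, gid)
    for (chrom in names(chrom_seq)) {
      seq <- chrom_seq[[chrom]]
      L <- nchar(seq)
      if (L < 23L) next
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else revcomp(seq)
        hits <- scan_strand(s, proto_chars, max_mismatches, pam_classes)
        if (nrow(hits) == 0L) next
        if (strand == "+") {
          start <- hits$i
        } else {
          start <- L - hits$i - 21L
        }
        hits$chrom <- chrom
        hits$start <- start
        hits$end <- start + 22L
        hits$strand <- strand
        hits$guide_id <- gid
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (length(out) == 0L) return(empty_sites())
  sites <- do.call(rbind, out)
  sites$score <- vapply(sites$mismatch_positions, function(mp) {
    p <- if (nzchar(mp)) as.integer(strsplit(mp, ",")[[1]]) else integer(0)
    specificity_score(p, model)
  }, numeric(1), USE.NAMES = FALSE)
  sites$is_on_target <- FALSE
  for (gi in seq_len(nrow(guides))) {
    loci <- guide_loci(guides, guides$id[gi])
    if (nrow(loci) == 0L) next
    key <- paste(guides$id[gi], loci$chrom, loci$start, loci$strand)
    skey <- paste(sites$guide_id, sites$chrom, sites$start, sites$strand)
    sites$is_on_target <- sites$is_on_target |
      (skey %in% key & sites$n_mismatch == 0L)
  }
  sites <- sites[order(sites$guide_id, sites$chrom, sites$start,
                       sites$strand), , drop = FALSE]
  sites$site_id <- sprintf("%s|%s:%d:%s", sites$guide_id, sites$chrom,
                           sites$start, sites$strand)
  rownames(sites) <- NULL
  sites[, names(empty_sites())]
}

# vectorized single-strand scan; returns window start i (1-based on the
# scanned strand), observed protospacer/PAM, class and mismatch bookkeeping
scan_strand <- function(seq, proto_chars, max_mm, pam_classes) {
  L <- nchar(seq)
  n_win <- L - 22L
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mm <- integer(n_win)
  has_n <- logical(n_win)
  for (j in 1:20) {
    sj <- chars[j:(j + n_win - 1L)]
    mm <- mm + (sj != proto_chars[j])
    has_n <- has_n | sj == "N"
  }
  p1 <- chars[21:(20L + n_win)]
  p2 <- chars[22:(21L + n_win)]
  p3 <- chars[23:(22L + n_win)]
  has_n <- has_n | p1 == "N" | p2 == "N" | p3 == "N"
  cls <- rep("none", n_win)
  cls[p2 == "G" & p3 == "G"] <- "NGG"
  cls[p2 == "A" & p3 == "G"] <- "NAG"
  cls[p2 == "G" & p3 == "A"] <- "NGA"
  keep <- !has_n & mm <= max_mm & cls %in% pam_classes
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(i = integer(), protospacer = character(),
                      pam = character(), pam_class = character(),
                      n_mismatch = integer(),
                      mismatch_positions = character(),
                      stringsAsFactors = FALSE))
  }
  mp <- vapply(idx, function(i) {
    win <- chars[i:(i + 19L)]
    paste(which(win != proto_chars), collapse = ",")
  }, character(1))
  data.frame(
    i = idx,
    protospacer = substring(seq, idx, idx + 19L),
    pam = substring(seq, idx + 20L, idx + 22L),
    pam_class = cls[idx],
    n_mismatch = mm[idx],
    mismatch_positions = mp,
    stringsAsFactors = FALSE
  )
}

#' Tally enumerated sites per guide and PAM class
#'
#' On-target entries are excluded from the off-target denominators by
#' default (flip with `include_on_target`). Every (guide, class)
#' combination is reported, zeros included, so the table can serve as
#' the denominator column of downstream ratio tables.
#'
#' @param sites site table from one [enumerate_offtargets()] run.
#' @param include_on_target count intended loci too (default FALSE).
#' @return data.frame (guide_id, pam_class, n_sites).
#' @export
summarize_by_pam <- function(sites, include_on_target = FALSE) {
  classes <- c("NGG", "NAG", "NGA")
  if (!include_on_target && nrow(sites) > 0L) {
    sites <- sites[!sites$is_on_target, , drop = FALSE]
  }
  guides <- unique(sites$guide_id)
  grid <- expand.grid(guide_id = guides, pam_class = classes,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    return(data.frame(guide_id = character(), pam_class = character(),
                      n_sites = integer()))
  }
  tab <- table(sites$guide_id, sites$pam_class)
  grid$n_sites <- mapply(function(g, p) {
    if (g %in% rownames(tab) && p %in% colnames(tab)) tab[g, p] else 0L
  }, grid$guide_id, grid$pam_class)
  grid <- grid[order(grid$guide_id, match(grid$pam_class, classes)), ]
  rownames(grid) <- NULL
  grid
}
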