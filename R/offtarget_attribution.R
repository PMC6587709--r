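variant_interval <- function(df) {
  # genomic footprint used for attribution: SNPs and insertion anchors are
  # a single base; deletions cover the deleted bases (anchor excluded)
  lr <- nchar(df$ref)
  start <- ifelse(df$vtype == "DEL", df$pos + 1L, df$pos)
  end <- ifelse(df$vtype %in% c("DEL", "MNP"), df$pos + lr - 1L, start)
  end <- pmax(start, end)
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Attribute private variants to off-target sites through flanks
#'
#' A variant is attributed to a site when its footprint (SNP position,
#' insertion anchor, or any deleted base) overlaps the site's 23-bp
#' interval extended by `flank` on both sides. All qualifying
#' (variant, site) pairs are reported; a variant hitting more than one
#' site is attributed to each and flagged `ambiguous`. On-target sites
#' are excluded from off-target attribution and reported separately.
#'
#' @param private variant data frame (or key vector) of private variants;
#'   a `sample` column is carried through when present.
#' @param sites site table from [enumerate_offtargets()].
#' @param flank flank width in bp (default 20).
#' @return list with `offtarget` and `ontarget` attribution tables
#'   (key, sample, site_id, guide_id, pam_class, distance, ambiguous).
#' @export
attribute_variants <- function(private, sites, flank = 20L) {
  stopifnot(flank >= 0L)
  if (is.character(private)) {
    private <- cbind(parse_variant_key(private), sample = NA_character_)
  }
  if (!"sample" %in% names(private)) private$sample <- NA_character_
  empty <- data.frame(key = character(), sample = character(),
                      site_id = character(), guide_id = character(),
                      pam_class = character(), distance = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (nrow(private) == 0L || nrow(sites) == 0L) {
    return(list(offtarget = empty, ontarget = empty))
  }
  vi <- variant_interval(private)
  vr <- GenomicRanges::GRanges(private$chrom,
                               IRanges::IRanges(vi$start, vi$end))
  sr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(pmax(1L, sites$start - flank),
                                                sites$end + flank))
  ov <- GenomicRanges::findOverlaps(vr, sr)
  if (length(ov) == 0L) return(list(offtarget = empty, ontarget = empty))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  inside <- pmax(sites$start[si] - vi$end[qi], vi$start[qi] - sites$end[si])
  distance <- pmax(0L, inside)
  hits <- data.frame(
    key = variant_key(private)[qi],
    sample = private$sample[qi],
    site_id = sites$site_id[si],
    guide_id = sites$guide_id[si],
    pam_class = sites$pam_class[si],
    distance = as.integer(distance),
    is_on_target = sites$is_on_target[si],
    stringsAsFactors = FALSE
  )
  # ambiguity is judged within the off-target universe per sample
  split_flag <- function(df) {
    if (nrow(df) == 0L) { df$ambiguous <- logical(0); return(df) }
    id <- paste(df$key, df$sample)
    df$ambiguous <- stats::ave(seq_along(id), id, FUN = length) > 1L
    df
  }
  off <- split_flag(hits[!hits$is_on_target, , drop = FALSE])
  on <- split_flag(hits[hits$is_on_target, , drop = FALSE])
  off$is_on_target <- NULL
  on$is_on_target <- NULL
  rownames(off) <- rownames(on) <- NULL
  list(offtarget = off, ontarget = on)
}

#' Per-guide, per-PAM-class mutation ratio table
#'
#' Ratio of distinct mutated off-target sites to enumerated sites per
#' (guide, PAM class), as a percentage rounded to 2 decimals, formatted
#' `hits/sites (ratio)`. Classes with a zero denominator are omitted.
#'
#' @param attributed off-target attribution table from
#'   [attribute_variants()].
#' @param site_counts denominator table from [summarize_by_pam()] of the
#'   same enumeration run.
#' @return data.frame (guide_id, pam_class, n_mutated_sites, n_sites,
#'   ratio_pct, label).
#' @export
mutation_ratio_table <- function(attributed, site_counts) {
  if (nrow(attributed) > 0L) {
    known <- paste(attributed$guide_id, attributed$pam_class) %in%
      paste(site_counts$guide_id, site_counts$pam_class)
    if (!all(known)) {
      stop("attributed hits reference (guide, PAM class) pairs absent from site_counts")
    }
  }
  out <- site_counts[site_counts$n_sites > 0L, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(data.frame(guide_id = character(), pam_class = character(),
                      n_mutated_sites = integer(), n_sites = integer(),
                      ratio_pct = numeric(), label = character()))
  }
  out$n_mutated_sites <- mapply(function(g, p) {
    sel <- attributed$guide_id == g & attributed$pam_class == p
    length(unique(attributed$site_id[sel]))
  }, out$guide_id, out$pam_class)
  out$ratio_pct <- round(100 * out$n_mutated_sites / out$n_sites, 2)
  out$label <- sprintf("%d/%d (%.2f)", out$n_mutated_sites, out$n_sites,
                       out$ratio_pct)
  rownames(out) <- NULL
  out
}
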