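#' Hard-filter thresholds
#'
#' Mirrors the GATK-style hard-filter disjunction used for the cohort
#' call sets: a record is dropped when `QD < qd_min`, or
#' `ReadPosRankSum < rprs_min`, or `FS > fs_max`, or `QUAL < qual_min`,
#' or `DP < depth_min`. `qual_min = NULL` means "mean QUAL of the
#' sample's raw call set", computed by [hard_filter()] before any record
#' is removed.
#'
#' @param qd_min quality-by-depth floor (default 20.0).
#' @param rprs_min ReadPosRankSum floor (default -8.0).
#' @param fs_max Fisher-strand ceiling (default 10.0).
#' @param qual_min site-quality floor; NULL = per-sample mean QUAL.
#' @param depth_min minimum depth (default 20).
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(qd_min = 20.0, rprs_min = -8.0, fs_max = 10.0,
                              qual_min = NULL, depth_min = 20) {
  stopifnot(depth_min >= 0)
  structure(list(qd_min = qd_min, rprs_min = rprs_min, fs_max = fs_max,
                 qual_min = qual_min, depth_min = depth_min),
            class = "filter_thresholds")
}

#' Apply the hard filters to one sample's call set
#'
#' Missing annotations do not fire their clause by default (the printed
#' disjunction cannot evaluate on an absent field); `strict_missing =
#' TRUE` drops records with any missing annotation instead.
#'
#' @param variants variant data frame (one sample; mean-QUAL is computed
#'   over this set when `qual_min` is NULL).
#' @param thresholds a [filter_thresholds()] object.
#' @param strict_missing drop records with missing annotations.
#' @return the retained subset of `variants`.
#' @export
hard_filter <- function(variants, thresholds = filter_thresholds(),
                        strict_missing = FALSE) {
  if (nrow(variants) == 0L) return(variants)
  qual_min <- thresholds$qual_min
  if (is.null(qual_min)) qual_min <- mean(variants$qual, na.rm = TRUE)
  clause <- function(x, test) {
    bad <- test(x)
    if (strict_missing) bad[is.na(bad)] <- TRUE else bad[is.na(bad)] <- FALSE
    bad
  }
  drop <- clause(variants$qd, function(x) x < thresholds$qd_min) |
    clause(variants$rprs, function(x) x < thresholds$rprs_min) |
    clause(variants$fs, function(x) x > thresholds$fs_max) |
    clause(variants$qual, function(x) x < qual_min) |
    clause(variants$dp, function(x) x < thresholds$depth_min)
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pre-existing (maternal) variant set
#'
#' The variants carried by the maternal cultivar relative to the
#' reference: the intersection of the wild-type plants' call sets.
#'
#' @param wt_sets list (length >= 2) of [variant_key()] vectors, one per
#'   WT plant.
#' @return character vector of shared keys.
#' @export
derive_preexisting <- function(wt_sets) {
  if (length(wt_sets) < 2L) stop("need at least two WT call sets")
  Reduce(intersect, wt_sets)
}

#' Private variants of one edited plant
#'
#' Implements the cohort subtraction cascade: the edited sample's keys
#' minus every WT set ("vs Ref/WT"), minus every NEGATIVE set
#' ("vs Ref/WT/Ne"), minus every other EDITED sample's set (private).
#'
#' A plant's own descendants share its variants by inheritance and are
#' therefore excluded from the "other edited samples" comparators —
#' otherwise a T0 plant's true private mutations would be masked by its
#' own T1 progeny. Ancestors stay in the comparator set, so inherited
#' keys can never be private to a progeny sample and private sets of
#' distinct samples remain disjoint.
#'
#' @param sample_id the edited sample.
#' @param sets named list of key vectors, one per sample in the design.
#' @param design cohort design table.
#' @return list with `private`, `minus_wt`, `minus_wt_ne` key vectors.
#' @export
derive_private <- function(sample_id, sets, design) {
  validate_design(design)
  if (!sample_id %in% names(sets)) stop("sample not in cohort: ", sample_id)
  if (!sample_id %in% design$sample_id) stop("sample not in design: ", sample_id)
  wt <- design$sample_id[design$role == "WT"]
  ne <- design$sample_id[design$role == "NEGATIVE"]
  if (length(wt) == 0L || length(ne) == 0L) {
    stop("cohort needs at least one WT and one NEGATIVE sample")
  }
  own <- sets[[sample_id]]
  minus_wt <- setdiff(own, unlist(sets[wt], use.names = FALSE))
  minus_wt_ne <- setdiff(minus_wt, unlist(sets[ne], use.names = FALSE))
  others <- setdiff(design$sample_id[design$role == "EDITED"],
                    c(sample_id, descendants_of(sample_id, design)))
  others <- intersect(others, names(sets))
  private <- setdiff(minus_wt_ne, unlist(sets[others], use.names = FALSE))
  list(private = private, minus_wt = minus_wt, minus_wt_ne = minus_wt_ne)
}

# descendants of a sample through parent_id links
descendants_of <- function(sample_id, design) {
  down <- sample_id
  repeat {
    kids <- design$sample_id[!is.na(design$parent_id) &
                               design$parent_id %in% down]
    new <- setdiff(kids, down)
    if (length(new) == 0L) break
    down <- c(down, new)
  }
  setdiff(down, sample_id)
}

#' Full cohort set arithmetic
#'
#' Runs [derive_preexisting()] and [derive_private()] across the cohort
#' and asserts the containment invariants (private within minus-WT/Ne
#' within minus-WT; pairwise-disjoint private sets; private disjoint
#' from pre-existing).
#'
#' @param sets named list of key vectors per sample.
#' @param design cohort design table.
#' @return list: `preexisting`, `negative_minus_wt` (per negative),
#'   `edited` (per edited sample: private / minus_wt / minus_wt_ne).
#' @export
cohort_sets <- function(sets, design) {
  validate_design(design)
  wt <- design$sample_id[design$role == "WT"]
  ne <- design$sample_id[design$role == "NEGATIVE"]
  ed <- design$sample_id[design$role == "EDITED"]
  if (length(wt) < 2L) stop("cohort needs >= 2 WT samples")
  preexisting <- derive_preexisting(unname(sets[wt]))
  wt_union <- unlist(sets[wt], use.names = FALSE)
  negative_minus_wt <- lapply(sets[ne], function(s) setdiff(s, wt_union))
  edited <- lapply(ed, function(s) derive_private(s, sets, design))
  names(edited) <- ed
  for (s in ed) {
    stopifnot(all(edited[[s]]$private %in% edited[[s]]$minus_wt_ne),
              all(edited[[s]]$minus_wt_ne %in% edited[[s]]$minus_wt),
              length(intersect(edited[[s]]$private, preexisting)) == 0L)
  }
  if (length(ed) >= 2L) {
    pr <- lapply(edited, `[[`, "private")
    for (i in seq_along(pr)) for (j in seq_len(i - 1L)) {
      stopifnot(length(intersect(pr[[i]], pr[[j]])) == 0L)
    }
  }
  list(preexisting = preexisting, negative_minus_wt = negative_minus_wt,
       edited = edited)
}

#' Overlap of negative-plant variation with edited plants
#'
#' Fraction of the negatives' (union) variant keys — split into SNP vs
#' indel — found in at least one edited sample; the somaclonal-sharing
#' signal.
#'
#' @param sets named list of key vectors per sample.
#' @param design cohort design table.
#' @return data.frame (class, n_negative, n_shared, fraction).
#' @export
overlap_fraction <- function(sets, design) {
  validate_design(design)
  ne <- design$sample_id[design$role == "NEGATIVE"]
  ed <- design$sample_id[design$role == "EDITED"]
  neg_union <- unique(unlist(sets[ne], use.names = FALSE))
  if (length(neg_union) == 0L) {
    stop("negative union is empty; overlap fraction undefined")
  }
  ed_union <- unique(unlist(sets[ed], use.names = FALSE))
  parsed <- parse_variant_key(neg_union)
  is_snp <- parsed$vtype == "SNP"
  tally <- function(keys) {
    n <- length(keys)
    k <- sum(keys %in% ed_union)
    data.frame(n_negative = n, n_shared = k,
               fraction = if (n > 0L) k / n else NA_real_)
  }
  out <- rbind(
    cbind(class = "SNP", tally(neg_union[is_snp])),
    cbind(class = "indel", tally(neg_union[!is_snp]))
  )
  out$class <- as.character(out$class)
  out
}

#' Base-substitution spectrum
#'
#' 4x4 matrix (rows = REF base, columns = ALT base) of percentages over
#' all SNPs; off-diagonal entries sum to 100.
#'
#' @param variants normalized variant data frame; non-SNP rows are an
#'   error.
#' @return numeric 4x4 matrix with dimnames A/C/G/T.
#' @export
substitution_spectrum <- function(variants) {
  if (nrow(variants) > 0L && any(variants$vtype != "SNP")) {
    stop("substitution_spectrum expects SNPs only")
  }
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 4, 4, dimnames = list(ref = bases, alt = bases))
  if (nrow(variants) == 0L) return(m)
  tab <- table(factor(variants$ref, bases), factor(variants$alt, bases))
  m[] <- 100 * as.numeric(tab) / sum(tab)
  m
}

#' Indel length histogram
#'
#' Length is `|len(ref) - len(alt)|`, reported signed by type:
#' insertions positive, deletions negative.
#'
#' @param variants normalized variant data frame; SNP/MNP rows ignored.
#' @return data.frame (vtype, length, signed_length, count) sorted by
#'   signed length.
#' @export
indel_length_hist <- function(variants) {
  ind <- variants[variants$vtype %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(ind) == 0L) {
    return(data.frame(vtype = character(), length = integer(),
                      signed_length = integer(), count = integer()))
  }
  len <- abs(nchar(ind$ref) - nchar(ind$alt))
  signed <- ifelse(ind$vtype == "INS", len, -len)
  tab <- table(signed, ind$vtype)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("signed_length", "vtype", "count")
  df <- df[df$count > 0L, , drop = FALSE]
  df$signed_length <- as.integer(df$signed_length)
  df$length <- abs(df$signed_length)
  df <- df[order(df$signed_length), c("vtype", "length", "signed_length", "count")]
  rownames(df) <- NULL
  df
}
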