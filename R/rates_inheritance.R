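#' Per-site mutation rate
#'
#' Rate per site per (tetraploid) genome: `n_variants / (genome_length *
#' ploidy_factor)`. The default ploidy factor of 4 reflects the
#' allotetraploid convention under which cohort-level rates are quoted
#' per site per tetraploid genome.
#'
#' @param n_variants variant count.
#' @param genome_length haploid genome length in bp.
#' @param ploidy_factor denominator multiplier (default 4).
#' @return a `rate_estimate` list with `rate` and a 3-significant-figure
#'   `rate_label`.
#' @export
mutation_rate <- function(n_variants, genome_length, ploidy_factor = 4) {
  if (genome_length <= 0 || ploidy_factor <= 0) {
    stop("genome_length and ploidy_factor must be positive")
  }
  if (n_variants < 0) stop("n_variants must be >= 0")
  rate <- n_variants / (genome_length * ploidy_factor)
  structure(list(n_variants = n_variants, genome_length = genome_length,
                 ploidy_factor = ploidy_factor, rate = rate,
                 rate_label = formatC(signif(rate, 3), format = "g")),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%d variants / (%g bp x %g) = %s per site per genome\n",
              x$n_variants, x$genome_length, x$ploidy_factor, x$rate_label))
  invisible(x)
}

#' Spontaneous mutations arising between generations
#'
#' Keys present in a T1 sample but absent from its T0 parent, minus the
#' pre-existing set and minus anything attributed to on- or off-target
#' sites. The exclusions are asserted on the result.
#'
#' @param t1_set T1 sample's key vector.
#' @param t0_parent_set the parent's key vector.
#' @param preexisting pre-existing key set from [derive_preexisting()].
#' @param attributed_edits keys attributed to sites (on- plus off-target).
#' @return character vector of spontaneous keys.
#' @export
spontaneous_variants <- function(t1_set, t0_parent_set,
                                 preexisting = character(0),
                                 attributed_edits = character(0)) {
  out <- setdiff(t1_set, t0_parent_set)
  out <- setdiff(out, preexisting)
  out <- setdiff(out, attributed_edits)
  stopifnot(length(intersect(out, preexisting)) == 0L,
            length(intersect(out, attributed_edits)) == 0L)
  out
}

#' Classify an observed allele against its reference allele
#'
#' Returns the compact edit code used in inheritance tables: `"no"` for
#' an identical allele, `"d<k>"` / `"i<k>"` for a single contiguous k-bp
#' deletion / insertion, `"s<k>"` for k substituted bases with no length
#' change, and `"complex"` otherwise. Deletions may be written either as
#' a shorter allele or with explicit `-` gap characters at the deleted
#' positions.
#'
#' @param ref_allele reference allele over the locus window.
#' @param observed_allele observed allele (may contain `-` gaps).
#' @return the type code string.
#' @export
classify_allele <- function(ref_allele, observed_allele) {
  ref <- toupper(ref_allele)
  obs <- toupper(observed_allele)
  if (!nzchar(ref) || !nzchar(obs)) stop("alleles must be non-empty")
  if (grepl("-", obs, fixed = TRUE)) {
    if (nchar(obs) != nchar(ref)) return("complex")
    gap <- which(strsplit(obs, "", fixed = TRUE)[[1]] == "-")
    contiguous <- length(gap) == (max(gap) - min(gap) + 1L)
    rest_match <- identical(
      strsplit(ref, "")[[1]][-gap], strsplit(obs, "")[[1]][-gap])
    if (contiguous && rest_match) return(paste0("d", length(gap)))
    return("complex")
  }
  if (identical(ref, obs)) return("no")
  lr <- nchar(ref)
  lo <- nchar(obs)
  if (lr == lo) {
    k <- sum(strsplit(ref, "")[[1]] != strsplit(obs, "")[[1]])
    return(paste0("s", k))
  }
  # single contiguous indel iff common prefix + common suffix cover the
  # shorter allele
  shorter <- if (lo < lr) obs else ref
  longer <- if (lo < lr) ref else obs
  k <- nchar(longer) - nchar(shorter)
  p <- common_prefix_len(shorter, longer)
  s <- common_suffix_len(shorter, longer)
  if (p + s >= nchar(shorter)) {
    return(paste0(if (lo < lr) "d" else "i", k))
  }
  "complex"
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ca <- strsplit(a, "")[[1]][seq_len(n)]
  cb <- strsplit(b, "")[[1]][seq_len(n)]
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

common_suffix_len <- function(a, b) {
  common_prefix_len(paste(rev(strsplit(a, "")[[1]]), collapse = ""),
                    paste(rev(strsplit(b, "")[[1]]), collapse = ""))
}

validate_calls <- function(calls) {
  need <- c("locus", "allele", "code", "sample", "generation", "count")
  if (!all(need %in% names(calls))) {
    stop("calls need columns: ", paste(need, collapse = ", "))
  }
  invisible(calls)
}

#' Cross-generation inheritance of on-target alleles
#'
#' For each (locus, allele): `transmitted` when evidence counts are
#' positive in both generations, `lost` when only in T0, `new` when only
#' in T1. Alleles with zero counts everywhere are dropped. The per-locus
#' summary flags loci where any edited (non-"no") allele is `new`. A
#' single supporting count is enough by default; raise `min_count` to
#' impose an evidence threshold.
#'
#' @param calls long-format call table: locus, allele, code, sample,
#'   generation (T0/T1), count.
#' @param min_count minimum per-generation evidence (default 1).
#' @return list with `alleles` (locus, allele, code, n_t0, n_t1, status)
#'   and `loci` (locus, any_new_edit).
#' @export
inheritance_table <- function(calls, min_count = 1L) {
  validate_calls(calls)
  agg <- stats::aggregate(count ~ locus + allele + code + generation,
                          data = calls, FUN = sum)
  key <- unique(agg[, c("locus", "allele", "code")])
  get_n <- function(l, a, gen) {
    sel <- agg$locus == l & agg$allele == a & agg$generation == gen
    if (any(sel)) sum(agg$count[sel]) else 0L
  }
  key$n_t0 <- mapply(get_n, key$locus, key$allele, MoreArgs = list(gen = "T0"))
  key$n_t1 <- mapply(get_n, key$locus, key$allele, MoreArgs = list(gen = "T1"))
  key <- key[key$n_t0 >= min_count | key$n_t1 >= min_count, , drop = FALSE]
  key$status <- ifelse(key$n_t0 >= min_count & key$n_t1 >= min_count,
                       "transmitted",
                       ifelse(key$n_t0 >= min_count, "lost", "new"))
  loci <- data.frame(locus = unique(key$locus), stringsAsFactors = FALSE)
  loci$any_new_edit <- vapply(loci$locus, function(l) {
    any(key$locus == l & key$status == "new" & key$code != "no")
  }, logical(1))
  rownames(key) <- NULL
  list(alleles = key, loci = loci)
}

#' Editing efficiency at a locus
#'
#' Fraction of evidence (clone or read counts) carrying a non-"no" type
#' code.
#'
#' @param calls call table restricted to one locus (extra loci are an
#'   error); columns code and count (and optionally sample/generation,
#'   ignored).
#' @return fraction in `[0, 1]`, or NA when total evidence is zero.
#' @export
editing_efficiency <- function(calls) {
  if (!all(c("code", "count") %in% names(calls))) {
    stop("calls need columns code and count")
  }
  if ("locus" %in% names(calls) && length(unique(calls$locus)) > 1L) {
    stop("editing_efficiency is per locus; got several")
  }
  total <- sum(calls$count)
  if (total == 0) return(NA_real_)
  sum(calls$count[calls$code != "no"]) / total
}

#' Read / write inheritance call tables
#'
#' @param path TSV with columns locus, allele, code, sample, generation,
#'   count.
#' @return call data.frame.
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_calls(df)
  df
}

#' @rdname read_calls
#' @param calls call table to write.
#' @export
write_calls <- function(calls, path) {
  validate_calls(calls)
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
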