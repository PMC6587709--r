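#' Apply variants to a reference genome
#'
#' Produces a "personalized" genome: SNPs substitute in place, indels
#' insert or delete bases and shift all downstream coordinates. The
#' returned object carries per-chromosome coordinate maps that convert
#' reference positions to personalized positions and back. Variants are
#' normalized (and therefore REF-checked) before application; two
#' variants altering the same reference base are rejected.
#'
#' @param genome reference genome.
#' @param variants variant data frame or [variant_key()] vector.
#' @return a `personalized_genome` list: `genome` (the personalized
#'   sequences), `variants` (as applied, normalized, sorted) and the
#'   internal maps.
#' @export
apply_variants <- function(genome, variants) {
  genome <- as_genome(genome)
  if (is.character(variants)) variants <- parse_variant_key(variants)
  if (nrow(variants) > 0L) {
    variants <- normalize_variants(variants, genome)
    variants <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  }
  chrom_seq <- as.character(genome)
  maps <- list()
  out_seq <- character(length(chrom_seq))
  names(out_seq) <- names(chrom_seq)
  for (chrom in names(chrom_seq)) {
    seq <- chrom_seq[[chrom]]
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    v <- v[order(v$pos, v$ref, v$alt), , drop = FALSE]
    if (nrow(v) == 0L) {
      out_seq[[chrom]] <- seq
      maps[[chrom]] <- empty_map()
      next
    }
    ref_len <- nchar(v$ref)
    alt_len <- nchar(v$alt)
    end <- v$pos + ref_len - 1L
    if (nrow(v) > 1L) {
      clash <- which(v$pos[-1L] <= end[-nrow(v)])
      if (length(clash) > 0L) {
        stop("conflicting variants on ", chrom, ": ",
             paste(variant_key(v[c(clash[1L], clash[1L] + 1L), ]),
                   collapse = " vs "))
      }
    }
    if (end[nrow(v)] > nchar(seq)) stop("variant extends past end of ", chrom)
    pieces <- character(2L * nrow(v) + 1L)
    prev <- 0L
    for (i in seq_len(nrow(v))) {
      pieces[2L * i - 1L] <- substring(seq, prev + 1L, v$pos[i] - 1L)
      pieces[2L * i] <- v$alt[i]
      prev <- end[i]
    }
    pieces[2L * nrow(v) + 1L] <- substring(seq, prev + 1L, nchar(seq))
    out_seq[[chrom]] <- paste(pieces, collapse = "")
    delta <- alt_len - ref_len
    cum <- cumsum(delta)
    maps[[chrom]] <- data.frame(
      pos = v$pos, ref_len = ref_len, alt_len = alt_len,
      end = end, ppos = v$pos + c(0L, cum[-length(cum)]), cum = cum
    )
  }
  structure(list(genome = as_genome(out_seq), variants = variants,
                 maps = maps,
                 chrom_len = setNames(nchar(chrom_seq), names(chrom_seq))),
            class = "personalized_genome")
}

empty_map <- function() {
  data.frame(pos = integer(), ref_len = integer(), alt_len = integer(),
             end = integer(), ppos = integer(), cum = integer())
}

invert_map <- function(map) {
  data.frame(pos = map$ppos, ref_len = map$alt_len, alt_len = map$ref_len,
             end = map$ppos + map$alt_len - 1L,
             ppos = map$pos, cum = -map$cum)
}

map_with <- function(map, pos) {
  out <- rep(NA_integer_, length(pos))
  if (nrow(map) == 0L) return(as.integer(pos))
  i <- findInterval(pos, map$pos)
  before <- i == 0L
  out[before] <- pos[before]
  inside <- !before & pos <= map$end[pmax(i, 1L)]
  after <- !before & !inside
  out[after] <- pos[after] + map$cum[i[after]]
  if (any(inside)) {
    ii <- i[inside]
    k <- pos[inside] - map$pos[ii]
    ok <- k < map$alt_len[ii]
    out[inside][ok] <- map$ppos[ii][ok] + k[ok]
  }
  as.integer(out)
}

#' Convert coordinates through a personalized genome
#'
#' Positions falling inside deleted reference bases (or, in the reverse
#' direction, inside inserted bases) are unmappable and return NA.
#'
#' @param pg a `personalized_genome` from [apply_variants()].
#' @param chrom chromosome name.
#' @param pos integer vector of 1-based positions.
#' @param direction `"ref2personal"` (default) or `"personal2ref"`.
#' @return integer vector of mapped positions (NA where unmappable).
#' @export
map_position <- function(pg, chrom, pos,
                         direction = c("ref2personal", "personal2ref")) {
  direction <- match.arg(direction)
  if (!chrom %in% names(pg$maps)) stop("unknown chromosome: ", chrom)
  map <- pg$maps[[chrom]]
  if (direction == "personal2ref") map <- invert_map(map)
  map_with(map, as.integer(pos))
}

count_mismatches <- function(observed, proto_chars) {
  # N never matches a protospacer base
  obs <- strsplit(observed, "", fixed = TRUE)[[1]]
  which(obs != proto_chars | obs == "N")
}

#' Re-assess off-target sites on a personalized genome
#'
#' Applies the (maternal) WT variant set to the reference, then for every
#' enumerated reference site that overlaps at least one variant
#' recomputes the 23-mer on the personalized sequence via the coordinate
#' map, recounts protospacer mismatches and reclassifies the PAM.
#' Additionally a full enumeration of the personalized genome is run;
#' personalized sites whose coordinates are not the image of any
#' reference site are reported as `novel_site`. Statuses per record
#' (semicolon-joined): `unchanged`, `mismatch_changed`, `pam_created`,
#' `pam_destroyed` (a PAM-class-to-class change sets both), `novel_site`,
#' `destroyed_site` (personalized mismatches exceed the budget, the PAM
#' no longer classifies, or the interval was deleted). Untouched sites
#' are omitted unless `full = TRUE`.
#'
#' @param guides guide table.
#' @param sites reference enumeration from [enumerate_offtargets()] for
#'   the same guides/genome.
#' @param wt_variants WT variant data frame or key vector (normalized or
#'   not; they are normalized here).
#' @param genome reference genome.
#' @param max_mismatches,pam_classes,model as in [enumerate_offtargets()].
#' @param full also report untouched sites with status `unchanged`.
#' @return data.frame of re-assessments: site_id, guide_id, chrom, strand,
#'   start_ref, start_personal, mismatches_ref, mismatches_personal,
#'   pam_ref, pam_personal, status, causal_variants.
#' @export
reassess_sites <- function(guides, sites, wt_variants, genome,
                           max_mismatches = 5L,
                           pam_classes = c("NGG", "NAG", "NGA"),
                           model = score_model(), full = FALSE) {
  genome <- as_genome(genome)
  pg <- apply_variants(genome, wt_variants)
  nv <- pg$variants
  keys <- variant_key(nv)
  pseq <- setNames(as.character(pg$genome), names(pg$genome))
  proto_of <- setNames(guides$protospacer, guides$id)
  vint <- if (nrow(nv) > 0L) {
    data.frame(chrom = nv$chrom, start = nv$pos,
               end = nv$pos + nchar(nv$ref) - 1L)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  causal_for <- function(chrom, start, end) {
    sel <- vint$chrom == chrom & vint$start <= end & vint$end >= start
    keys[sel]
  }
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    causal <- causal_for(st$chrom, st$start, st$end)
    if (length(causal) == 0L && !full) next
    proto_chars <- strsplit(proto_of[[st$guide_id]], "", fixed = TRUE)[[1]]
    ms <- map_position(pg, st$chrom, st$start)
    status <- character(0)
    mm_p <- NA_integer_
    pam_p <- NA_character_
    if (is.na(ms) || ms + 22L > nchar(pseq[[st$chrom]])) {
      status <- "destroyed_site"
    } else {
      window <- substring(pseq[[st$chrom]], ms, ms + 22L)
      if (st$strand == "-") window <- revcomp(window)
      mm_p <- length(count_mismatches(substring(window, 1L, 20L), proto_chars))
      pam_p <- substring(window, 21L, 23L)
      cls_p <- classify_pam(pam_p)
      cls_r <- st$pam_class
      if (mm_p != st$n_mismatch) status <- c(status, "mismatch_changed")
      if (cls_p != cls_r) {
        status <- c(status, "pam_destroyed")
        if (cls_p != "none") status <- c(status, "pam_created")
      }
      if (mm_p > max_mismatches || !cls_p %in% pam_classes) {
        status <- c(status, "destroyed_site")
      }
      if (length(status) == 0L) status <- "unchanged"
    }
    if (identical(status, "unchanged") && !full) next
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = st$site_id, guide_id = st$guide_id, chrom = st$chrom,
      strand = st$strand, start_ref = st$start, start_personal = ms,
      mismatches_ref = st$n_mismatch, mismatches_personal = mm_p,
      pam_ref = st$pam, pam_personal = pam_p,
      status = paste(unique(status), collapse = ";"),
      causal_variants = paste(causal, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  # full re-enumeration: personalized-only coordinates are novel sites
  psites <- enumerate_offtargets(pg$genome, guides, max_mismatches,
                                 pam_classes, model)
  if (nrow(psites) > 0L) {
    image_key <- vapply(seq_len(nrow(sites)), function(i) {
      ms <- map_position(pg, sites$chrom[i], sites$start[i])
      if (is.na(ms)) return(NA_character_)
      paste(sites$guide_id[i], sites$chrom[i], ms, sites$strand[i])
    }, character(1))
    pkey <- paste(psites$guide_id, psites$chrom, psites$start, psites$strand)
    novel <- psites[!pkey %in% image_key, , drop = FALSE]
    rseq <- setNames(as.character(genome), names(genome))
    for (i in seq_len(nrow(novel))) {
      st <- novel[i, ]
      proto_chars <- strsplit(proto_of[[st$guide_id]], "", fixed = TRUE)[[1]]
      # back-map the personalized window to locate reference context
      rpos <- map_position(pg, st$chrom, st$start:st$end,
                           direction = "personal2ref")
      rpos <- rpos[!is.na(rpos)]
      mm_r <- NA_integer_
      pam_r <- NA_character_
      causal <- character(0)
      if (length(rpos) > 0L) {
        r1 <- min(rpos); r2 <- max(rpos)
        causal <- causal_for(st$chrom, r1 - 1L, r2 + 1L)
        if (r2 - r1 == 22L && r2 <= nchar(rseq[[st$chrom]])) {
          window <- substring(rseq[[st$chrom]], r1, r2)
          if (st$strand == "-") window <- revcomp(window)
          mm_r <- length(count_mismatches(substring(window, 1L, 20L),
                                          proto_chars))
          pam_r <- substring(window, 21L, 23L)
        }
      }
      status <- "novel_site"
      if (!is.na(pam_r) && classify_pam(pam_r) == "none" &&
          st$pam_class != "none") {
        status <- c(status, "pam_created")
      }
      stopifnot(length(causal) >= 1L)  # every novel site must be explained
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("novel|%s|%s:%d:%s", st$guide_id, st$chrom,
                          st$start, st$strand),
        guide_id = st$guide_id, chrom = st$chrom, strand = st$strand,
        start_ref = if (length(rpos) > 0L) min(rpos) else NA_integer_,
        start_personal = st$start,
        mismatches_ref = mm_r, mismatches_personal = st$n_mismatch,
        pam_ref = pam_r, pam_personal = st$pam,
        status = paste(unique(status), collapse = ";"),
        causal_variants = paste(causal, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(site_id = character(), guide_id = character(),
                      chrom = character(), strand = character(),
                      start_ref = integer(), start_personal = integer(),
                      mismatches_ref = integer(),
                      mismatches_personal = integer(),
                      pam_ref = character(), pam_personal = character(),
                      status = character(), causal_variants = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test a re-assessment record for a status flag
#'
#' @param reassessments table from [reassess_sites()].
#' @param flag one of the status names.
#' @return logical vector.
#' @export
has_status <- function(reassessments, flag) {
  vapply(strsplit(reassessments$status, ";", fixed = TRUE),
         function(s) flag %in% s, logical(1))
}

#' Novel-site / PAM-alteration summary table
#'
#' Two rows per (guide, PAM class): the count of novel off-target sites
#' and the count of PAM alterations (created or destroyed), each over
#' the reference enumeration total for that class, formatted `n/total`.
#'
#' @param reassessments table from [reassess_sites()].
#' @param site_counts reference denominators from [summarize_by_pam()].
#' @return data.frame (guide_id, pam_class, level, n, total, label).
#' @export
novel_site_table <- function(reassessments, site_counts) {
  out <- site_counts
  novel <- reassessments[has_status(reassessments, "novel_site"), , drop = FALSE]
  pam_alt <- reassessments[has_status(reassessments, "pam_created") |
                             has_status(reassessments, "pam_destroyed"), ,
                           drop = FALSE]
  count_by <- function(df, class_col) {
    if (nrow(df) == 0L) return(function(g, p) 0L)
    cls <- classify_pam(ifelse(is.na(df[[class_col]]), "AAA", df[[class_col]]))
    function(g, p) sum(df$guide_id == g & cls == p)
  }
  n_novel <- count_by(novel, "pam_personal")
  n_pam <- count_by(pam_alt, "pam_ref")
  site_rows <- out
  site_rows$level <- "site"
  site_rows$n <- mapply(n_novel, out$guide_id, out$pam_class)
  pam_rows <- out
  pam_rows$level <- "pam"
  pam_rows$n <- mapply(n_pam, out$guide_id, out$pam_class)
  res <- rbind(site_rows, pam_rows)
  res$total <- res$n_sites
  res$n_sites <- NULL
  res$label <- sprintf("%d/%d", res$n, res$total)
  res <- res[order(res$guide_id, match(res$pam_class, c("NGG", "NAG", "NGA")),
                   match(res$level, c("site", "pam"))), ]
  rownames(res) <- NULL
  res
}
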