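#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
#' @importFrom methods is
NULL

GENOME_ALPHABET <- c("A", "C", "G", "T", "N")

#' Build a genome object from named sequences
#'
#' A genome is a named [Biostrings::DNAStringSet] with unique, non-empty
#' chromosome names and sequences restricted to the alphabet A, C, G, T, N.
#' Lowercase (soft-masked) bases are uppercased on construction.
#'
#' @param seqs named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return a validated `DNAStringSet`.
#' @export
as_genome <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (!methods::is(seqs, "DNAStringSet")) {
    stop("genome must be a character vector or DNAStringSet")
  }
  validate_genome(seqs)
  seqs
}

validate_genome <- function(genome) {
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm))) stop("chromosome names must be non-empty")
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  if (any(Biostrings::width(genome) == 0L)) stop("chromosome sequences must be non-empty")
  counts <- Biostrings::alphabetFrequency(genome)
  allowed <- colnames(counts) %in% GENOME_ALPHABET
  if (any(counts[, !allowed, drop = FALSE] > 0)) {
    stop("genome alphabet restricted to A, C, G, T, N")
  }
  invisible(genome)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (plain text).
#' @return a genome (`DNAStringSet`), uppercased and validated.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gn <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the record name
  names(gn) <- vapply(strsplit(names(gn), "\\s+"), `[`, character(1), 1L)
  as_genome(as.character(gn))
}

#' Write a genome to FASTA
#'
#' @param genome a genome object.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 70L)
  invisible(path)
}

## ---- variants ---------------------------------------------------------

variant_columns <- c("sample", "chrom", "pos", "ref", "alt", "vtype",
                     "qual", "qd", "fs", "rprs", "dp", "gt")

#' Construct a variant table
#'
#' Variants are plain data frames with one row per (sample, record):
#' `chrom`, 1-based `pos` of the first REF base, `ref`/`alt` allele strings,
#' `vtype` (SNP/INS/DEL/MNP), phred `qual`, caller annotations `qd`, `fs`,
#' `rprs` (ReadPosRankSum), `dp`, the genotype string `gt` and `sample`.
#'
#' @param chrom,pos,ref,alt,sample required fields.
#' @param qual,qd,fs,rprs,dp,gt optional annotations (NA when absent).
#' @return data.frame of variants.
#' @export
variant_frame <- function(chrom, pos, ref, alt, sample = NA_character_,
                          qual = NA_real_, qd = NA_real_, fs = NA_real_,
                          rprs = NA_real_, dp = NA_real_, gt = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    sample = rep_len(as.character(sample), n),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    vtype = rep(NA_character_, n),
    qual = rep_len(as.numeric(qual), n),
    qd = rep_len(as.numeric(qd), n),
    fs = rep_len(as.numeric(fs), n),
    rprs = rep_len(as.numeric(rprs), n),
    dp = rep_len(as.numeric(dp), n),
    gt = rep_len(as.character(gt), n),
    stringsAsFactors = FALSE
  )
  df$vtype <- variant_type(df$ref, df$alt)
  if (any(df$pos < 1L, na.rm = TRUE)) stop("variant pos must be >= 1")
  if (any(df$ref == df$alt & !grepl(",", df$alt))) stop("ref and alt must differ")
  df
}

#' Classify a ref/alt pair as SNP, INS, DEL or MNP
#'
#' Multi-allelic records (comma in `alt`) are typed NA until split by
#' [normalize_variants()].
#'
#' @param ref,alt allele strings.
#' @return character vector of types.
#' @export
variant_type <- function(ref, alt) {
  out <- rep(NA_character_, length(ref))
  multi <- grepl(",", alt)
  lr <- nchar(ref)
  la <- nchar(alt)
  out[!multi & lr == 1L & la == 1L] <- "SNP"
  out[!multi & la > lr] <- "INS"
  out[!multi & lr > la] <- "DEL"
  out[!multi & lr == la & lr > 1L] <- "MNP"
  out
}

#' Sample-independent variant identity
#'
#' The key `chrom:pos:ref:alt` defines "same genotype" for all cohort set
#' arithmetic (zygosity is deliberately ignored; see the methods vignette).
#' Keys are only meaningful for normalized variants.
#'
#' @param variants a variant data frame (or vectors via `chrom`...).
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Parse variant keys back into a table
#'
#' @param keys character keys produced by [variant_key()].
#' @return data.frame with chrom, pos, ref, alt, vtype.
#' @export
parse_variant_key <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character()))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed variant key: ", keys[which(bad)[1]])
  df <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    ref = vapply(parts, `[`, character(1), 3L),
    alt = vapply(parts, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  df$vtype <- variant_type(df$ref, df$alt)
  df
}

## ---- normalization ----------------------------------------------------

#' Normalize variants against a reference genome
#'
#' Splits multi-allelic records into one row per ALT, verifies the REF
#' allele against the genome, trims shared suffix then prefix bases
#' (keeping one anchor base for indels) and left-aligns indels through
#' homopolymer/repeat context. Normalization is idempotent, so equivalent
#' representations of the same indel collapse to a single [variant_key()].
#'
#' @param variants variant data frame.
#' @param genome the reference the variants were called on.
#' @return normalized variant data frame (possibly more rows than input).
#' @export
normalize_variants <- function(variants, genome) {
  genome <- as_genome(genome)
  if (nrow(variants) == 0L) return(variants)
  chrom_seq <- setNames(as.character(genome), names(genome))
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    if (!v$chrom %in% names(chrom_seq)) {
      stop("unknown chromosome in variant: ", v$chrom)
    }
    seq <- chrom_seq[[v$chrom]]
    alts <- strsplit(v$alt, ",", fixed = TRUE)[[1]]
    sub <- lapply(alts, function(a) {
      nv <- v
      nv$alt <- a
      norm1(nv, seq)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  out$vtype <- variant_type(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

# single-record trim + left-align (vt-style); seq is the chromosome string
norm1 <- function(v, seq) {
  pos <- v$pos
  ref <- v$ref
  alt <- v$alt
  obs <- substring(seq, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref)) {
    stop(sprintf("REF mismatch at %s:%d: genome has '%s', variant says '%s'",
                 v$chrom, pos, obs, ref))
  }
  last <- function(x) substring(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt)) {
      if (nchar(ref) == 1L || nchar(alt) == 1L) {
        if (pos == 1L) break
        base <- substring(seq, pos - 1L, pos - 1L)
        ref <- paste0(base, substring(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(base, substring(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
      } else {
        ref <- substring(ref, 1L, nchar(ref) - 1L)
        alt <- substring(alt, 1L, nchar(alt) - 1L)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  v$pos <- pos
  v$ref <- ref
  v$alt <- alt
  v
}

## ---- VCF --------------------------------------------------------------

#' Read a single-sample VCF v4.2 into a variant table
#'
#' Parsing is delegated to \pkg{vcfR}; INFO keys QD, FS and ReadPosRankSum
#' and FORMAT fields GT and DP are lifted into columns. Records are
#' returned as stored (normalize explicitly with [normalize_variants()]).
#'
#' @param path VCF file.
#' @param sample sample id to stamp on the records; defaults to the VCF
#'   sample column name.
#' @return variant data frame.
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0L) {
    return(variant_frame(character(), integer(), character(), character()))
  }
  n <- nrow(fix)
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  qd <- num_or_na(vcfR::extract.info(vcf, element = "QD"))
  fs <- num_or_na(vcfR::extract.info(vcf, element = "FS"))
  rprs <- num_or_na(vcfR::extract.info(vcf, element = "ReadPosRankSum"))
  gt <- rep(NA_character_, n)
  dp <- rep(NA_real_, n)
  if (ncol(vcf@gt) >= 2L) {
    if (is.null(sample)) sample <- colnames(vcf@gt)[2L]
    gtm <- vcfR::extract.gt(vcf, element = "GT")
    dpm <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    if (!is.null(gtm)) gt <- unname(gtm[, 1L])
    if (!is.null(dpm)) dp <- unname(dpm[, 1L])
  }
  if (is.null(sample)) sample <- tools::file_path_sans_ext(basename(path))
  variant_frame(
    chrom = unname(fix[, "CHROM"]), pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
    sample = sample, qual = num_or_na(fix[, "QUAL"]),
    qd = qd, fs = fs, rprs = rprs, dp = dp, gt = gt
  )
}

#' Write a variant table as a single-sample VCF v4.2
#'
#' @param variants variant data frame for one sample.
#' @param path output path.
#' @param sample sample column name; defaults to the table's sample id.
#' @export
write_vcf <- function(variants, path, sample = NULL) {
  if (is.null(sample)) {
    sample <- if (nrow(variants) > 0L) variants$sample[1L] else "SAMPLE"
  }
  if (nrow(variants) > 0L && length(unique(variants$sample)) > 1L) {
    stop("write_vcf expects a single sample per file")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=crisprtriage",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                formatC(x, format = "g", digits = 6))
  lines <- character(0)
  if (nrow(variants) > 0L) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    v <- variants[ord, , drop = FALSE]
    info <- vapply(seq_len(nrow(v)), function(i) {
      kv <- c(QD = fmt_num(v$qd[i]), FS = fmt_num(v$fs[i]),
              ReadPosRankSum = fmt_num(v$rprs[i]))
      kv <- kv[!is.na(kv)]
      if (length(kv) == 0L) "." else paste(names(kv), kv, sep = "=", collapse = ";")
    }, character(1))
    gt <- ifelse(is.na(v$gt), "./.", v$gt)
    dp <- ifelse(is.na(v$dp), ".", format(as.integer(v$dp)))
    qual <- ifelse(is.na(v$qual), ".", fmt_num(v$qual))
    lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, ".", info,
                   "GT:DP", paste(gt, dp, sep = ":"), sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

## ---- BED --------------------------------------------------------------

#' Write off-target sites as BED6
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention. Score column carries the specificity score.
#'
#' @param sites site table from [enumerate_offtargets()].
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(sites$chrom, sites$start - 1L, sites$end,
                 sites$site_id, round(sites$score, 2), sites$strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## ---- cohort design ----------------------------------------------------

#' Construct a cohort design table
#'
#' One row per sequenced plant: `sample_id`, `role` (WT / NEGATIVE /
#' EDITED), comma-separated `guide_ids` (empty unless EDITED),
#' `generation` (T0 / T1) and `parent_id` (required for T1).
#'
#' @param sample_id,role,guide_ids,generation,parent_id vectors, recycled.
#' @return validated design data.frame.
#' @export
cohort_design <- function(sample_id, role, guide_ids = "", generation = "T0",
                          parent_id = NA_character_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    role = toupper(as.character(role)),
    guide_ids = rep_len(as.character(guide_ids), length(sample_id)),
    generation = rep_len(toupper(as.character(generation)), length(sample_id)),
    parent_id = rep_len(as.character(parent_id), length(sample_id)),
    stringsAsFactors = FALSE
  )
  validate_design(df)
  df
}

validate_design <- function(design) {
  stopifnot(all(c("sample_id", "role", "guide_ids", "generation", "parent_id")
                %in% names(design)))
  if (anyDuplicated(design$sample_id)) stop("sample ids must be unique")
  if (!all(design$role %in% c("WT", "NEGATIVE", "EDITED"))) {
    stop("role must be WT, NEGATIVE or EDITED")
  }
  if (!all(design$generation %in% c("T0", "T1"))) {
    stop("generation must be T0 or T1")
  }
  t1 <- design$generation == "T1"
  if (any(t1 & (is.na(design$parent_id) | !nzchar(design$parent_id)))) {
    stop("every T1 sample needs a parent_id")
  }
  if (!all(design$parent_id[t1] %in% design$sample_id)) {
    stop("T1 parent_id must name a sample in the design")
  }
  has_guides <- !is.na(design$guide_ids) & nzchar(design$guide_ids)
  if (any(has_guides & design$role != "EDITED") ||
      any(!has_guides & design$role == "EDITED")) {
    stop("guide_ids must be non-empty iff role is EDITED")
  }
  invisible(design)
}

#' @rdname cohort_design
#' @param path TSV file with the design columns.
#' @export
read_cohort_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                   colClasses = "character")
  df$guide_ids[is.na(df$guide_ids)] <- ""
  validate_design(df)
  df
}

#' @rdname cohort_design
#' @param design design table to write.
#' @export
write_cohort_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_guides <- function(design, sample_id) {
  g <- design$guide_ids[design$sample_id == sample_id]
  if (length(g) == 0L) stop("unknown sample: ", sample_id)
  if (!nzchar(g)) character(0) else strsplit(g, ",", fixed = TRUE)[[1]]
}

## ---- guide files ------------------------------------------------------

#' Read / write guide definition tables
#'
#' Guide TSVs have columns id, protospacer (20 nt), pam (pattern, e.g.
#' NGG), gene, and loci — intended target loci encoded as
#' `chrom:start:strand` triples separated by `;`, where `start` is the
#' 1-based first position of the 23-bp protospacer+PAM window on the plus
#' strand.
#'
#' @param path TSV path.
#' @return guide data.frame.
#' @export
read_guides <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df$loci[is.na(df$loci)] <- ""
  validate_guides(df)
  df
}

#' @rdname read_guides
#' @param guides guide table.
#' @export
write_guides <- function(guides, path) {
  write.table(guides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a guide table row
#'
#' @param id guide identifier.
#' @param protospacer 20-nt spacer sequence (no PAM).
#' @param pam PAM pattern, default canonical NGG.
#' @param gene target-gene label.
#' @param loci data.frame (chrom, start, strand) of intended 23-bp windows,
#'   or an encoded string.
#' @export
guide <- function(id, protospacer, pam = "NGG", gene = NA_character_,
                  loci = "") {
  if (is.data.frame(loci)) loci <- encode_loci(loci)
  df <- data.frame(id = id, protospacer = toupper(protospacer), pam = pam,
                   gene = gene, loci = loci, stringsAsFactors = FALSE)
  validate_guides(df)
  df
}

validate_guides <- function(guides) {
  stopifnot(all(c("id", "protospacer", "pam", "loci") %in% names(guides)))
  if (anyDuplicated(guides$id)) stop("guide ids must be unique")
  bad <- nchar(guides$protospacer) != 20L |
    grepl("[^ACGT]", guides$protospacer)
  if (any(bad)) stop("protospacer must be exactly 20 nt over A/C/G/T")
  invisible(guides)
}

encode_loci <- function(df) {
  if (nrow(df) == 0L) return("")
  paste(df$chrom, df$start, df$strand, sep = ":", collapse = ";")
}

#' Parse the intended loci of one guide
#'
#' @param guides guide table.
#' @param id guide id.
#' @return data.frame (chrom, start, strand); zero rows when none.
#' @export
guide_loci <- function(guides, id) {
  row <- guides[guides$id == id, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown guide: ", id)
  s <- row$loci[1L]
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}
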