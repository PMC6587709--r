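#' GC fraction of a nucleotide sequence
#'
#' @param seq non-empty string over A/C/G/T.
#' @return (#G + #C) / length, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    stop("gc_content is defined over A/C/G/T only")
  }
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Position-specific mismatch penalty weights
#'
#' The experimentally derived per-position penalty vector of the
#' widely used Cas9 specificity scoring scheme (Hsu-style weights).
#' Position 1 is the PAM-distal end of the protospacer, position 20
#' PAM-proximal; PAM-proximal ("seed") mismatches are penalized most.
#'
#' @return numeric vector of 20 weights in `[0, 1]`.
#' @export
hsu_weights <- function() {
  c(0, 0, 0.014, 0, 0, 0.395, 0.317, 0, 0.389, 0.079,
    0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804, 0.685, 0.583)
}

#' Specificity score model
#'
#' @param weights 20 per-position penalties in `[0, 1]`; defaults to
#'   [hsu_weights()].
#' @return a `score_model` list.
#' @export
score_model <- function(weights = hsu_weights()) {
  weights <- as.numeric(weights)
  if (length(weights) != 20L || any(weights < 0 | weights > 1)) {
    stop("score model needs 20 weights in [0, 1]")
  }
  structure(list(weights = weights), class = "score_model")
}

#' Per-site specificity score
#'
#' Position-weighted score on a 0–100 scale, 100 = perfect match:
#' \deqn{100 \prod_p (1 - W_p) \times \frac{1}{\frac{19 - \bar d}{19} \cdot 4 + 1}
#'       \times \frac{1}{n^2}}
#' where the product runs over mismatched positions, \eqn{n} is the number
#' of mismatches and \eqn{\bar d} the mean distance between consecutive
#' mismatch positions; the two aggregation terms apply only for
#' \eqn{n \ge 2}. Position 1 is PAM-distal (see [hsu_weights()]); PAM
#' bases are not counted as mismatches.
#'
#' @param mismatch_positions strictly increasing integers in 1..20.
#' @param model a [score_model()].
#' @return score in `[0, 100]`.
#' @export
specificity_score <- function(mismatch_positions, model = score_model()) {
  p <- as.integer(mismatch_positions)
  if (any(p < 1L | p > 20L)) stop("mismatch positions must lie in 1..20")
  if (is.unsorted(p, strictly = TRUE)) stop("positions must be strictly increasing")
  n <- length(p)
  if (n == 0L) return(100)
  w <- model$weights
  s <- 100 * prod(1 - w[p])
  if (n >= 2L) {
    dbar <- mean(diff(p))
    s <- s * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / n^2)
  }
  s
}

#' Placeholder on-target activity scorer
#'
#' The on-target activity model used during the original guide selection
#' is a proprietary web-tool score that is not re-implemented here; any
#' candidate passing the GC gate receives 1.0 from this stub so the
#' `> on_score_min` gate is a no-op until a real scorer is supplied.
#' Reports produced with the stub are flagged as using a surrogate score.
#'
#' @param protospacer 20-nt candidate (ignored).
#' @return 1.0.
#' @export
stub_on_target_score <- function(protospacer) {
  rep(1.0, length(protospacer))
}

#' Scan a region for candidate guides
#'
#' Finds every 20-mer immediately 5' of an NGG PAM, on either strand,
#' that passes the GC-content window and the on-target score gate.
#'
#' @param region nucleotide string (>= 23 bp) to scan.
#' @param gc_min,gc_max GC-content window (defaults 0.40–0.60).
#' @param on_score_min on-target score gate (default 0.6).
#' @param scorer function(protospacer) -> score; defaults to
#'   [stub_on_target_score()].
#' @param chrom,offset optional coordinates of the region: `offset` is the
#'   1-based genomic position of the first region base.
#' @return data.frame of candidates: protospacer, pam, start (1-based first
#'   position of the 23-bp window on the plus strand), strand, gc,
#'   on_score, score_is_stub; sorted by position then strand.
#' @export
find_candidate_guides <- function(region, gc_min = 0.40, gc_max = 0.60,
                                  on_score_min = 0.6,
                                  scorer = stub_on_target_score,
                                  chrom = NA_character_, offset = 1L) {
  region <- toupper(as.character(region))
  if (nchar(region) < 23L) stop("region must be at least 23 bp")
  is_stub <- identical(scorer, stub_on_target_score)
  hits <- list()
  scan <- function(seq, strand) {
    L <- nchar(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (i in seq_len(L - 22L)) {
      if (chars[i + 21L] == "G" && chars[i + 22L] == "G") {
        proto <- substring(seq, i, i + 19L)
        if (grepl("[^ACGT]", proto)) next
        gc <- gc_content(proto)
        if (gc < gc_min || gc > gc_max) next
        sc <- scorer(proto)
        if (!(sc > on_score_min)) next
        start_plus <- if (strand == "+") i else L - i - 21L
        hits[[length(hits) + 1L]] <<- data.frame(
          protospacer = proto,
          pam = substring(seq, i + 20L, i + 22L),
          start = start_plus + offset - 1L,
          strand = strand, gc = gc, on_score = sc,
          score_is_stub = is_stub, stringsAsFactors = FALSE
        )
      }
    }
  }
  scan(region, "+")
  scan(revcomp(region), "-")
  if (length(hits) == 0L) {
    return(data.frame(protospacer = character(), pam = character(),
                      start = integer(), strand = character(), gc = numeric(),
                      on_score = numeric(), score_is_stub = logical()))
  }
  out <- do.call(rbind, hits)
  out$chrom <- chrom
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param seq string over A/C/G/T/N.
#' @return reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
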