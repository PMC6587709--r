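---
title: "Methods: separating Cas9 off-target mutations from inherent and somaclonal variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating Cas9 off-target mutations from inherent and somaclonal variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtriage)
```

## The inference problem

A whole-genome-sequenced cohort of Cas9-edited plants carries variants from
four causally distinct sources: (i) *pre-existing (inherent) variation* — the
maternal cultivar simply differs from the reference assembly it was aligned
to; (ii) *somaclonal variation* acquired during tissue culture and
regeneration, which affects negative (transformed but T-DNA-free) regenerants
just as much as edited ones; (iii) *spontaneous germline mutation* between
generations; and (iv) genuine *Cas9 activity*, on-target and off-target. Only
the last class is attributable to the nuclease, and in practice it is by far
the smallest. The package implements the cohort arithmetic, site enumeration
and re-assessment machinery needed to make that attribution defensible, plus
a truth-labelled simulator so every stage can be validated end to end.

The design assumes the standard cohort layout: several wild-type (WT)
plants of the transformation cultivar, several negative regenerants, a
panel of edited T0 plants (possibly targeting different guides), and
optionally T1 progeny of one T0 parent.

## The pipeline

1. **Hard filtering** (`hard_filter`). Records failing the GATK-style
   disjunction `QD < 20 || ReadPosRankSum < -8 || FS > 10 || QUAL <
   mean(QUAL) || DP < 20` are dropped. The mean-QUAL threshold is computed
   per sample over the *pre-filter* call set — the only self-contained
   reading of a mean-quality clause. Records with a missing annotation pass
   by default, because a disjunction over absent fields cannot evaluate; a
   `strict_missing` mode drops them instead.
2. **Normalization** (`normalize_variants`). Multi-allelic records are
   split, alleles are parsimony-trimmed (shared suffix then prefix, one
   anchor base retained for indels) and indels are left-aligned through
   repeat context. After normalization, variant identity is the key
   `(chrom, pos, ref, alt)`; equivalent indel representations collapse to
   one key, which is what makes the set arithmetic below well defined.
   Genotype/zygosity is deliberately ignored in cross-sample identity
   (the published protocol's "same genotype" is not defined at the
   zygosity level); a zygosity-aware comparison can be layered on top of
   the keys if needed.
3. **Cohort set cascade** (`cohort_sets`, `derive_private`). Pre-existing
   variation is the intersection of the WT call sets. For each edited
   plant, keys are subtracted in the published order: minus every WT set
   ("vs Ref/WT"), minus every negative set ("vs Ref/WT/Ne"), minus every
   other edited plant's set, leaving its *private* variants. One
   refinement: a plant's own descendants are excluded from the "other
   edited plants" comparators, since inherited variants would otherwise
   mask every heritable private mutation of the parent. Ancestors remain
   comparators, so an inherited key can never be private to a progeny
   sample and private sets stay pairwise disjoint. The cross-generation
   analysis below handles the T0/T1 comparison explicitly.
4. **Site enumeration** (`enumerate_offtargets`). Every 23-bp window on
   either strand whose trailing PAM classifies as NGG, NAG or NGA and
   whose leading 20-mer matches the guide with at most five mismatches.
   The engine is a vectorized position-wise scan; its contract is fixed
   by a naive position-by-position oracle that the test-suite re-checks on
   random genomes. Windows containing N are excluded, incomplete windows
   at chromosome edges are skipped, overlapping sites are all reported.
5. **Attribution** (`attribute_variants`). A private variant is tied to a
   site when its footprint falls within the site's 23 bp ± a 20-bp flank.
   Insertions count through their anchor base; deletions through any
   deleted base, so a long deletion sweeping into a flank is not missed.
   A variant reaching two flanked sites is reported against both and
   flagged ambiguous — no tie-break is defensible from first principles.
   The per-hit `distance` column (0 inside the site proper) lets users
   apply the stricter "inside the 23-mer" reading.
6. **Variant-aware re-assessment** (`reassess_sites`). The pre-existing
   (WT-intersection) set is applied to the reference; every site touched
   by a variant is re-extracted through the coordinate map, its
   mismatches recounted and its PAM reclassified. Novel sites are found
   by full re-enumeration of the personalized genome rather than by
   patching known sites, so sites created de novo by indels are caught;
   a personalized site is novel precisely when its coordinates are not
   the image of any reference site. Intersection-of-WT is the default
   personalization set because the genome-wide question is about the
   cultivar, not one plant; per-plant sets can be passed instead.
   Conflicting variants (two records altering the same base) are
   rejected, not arbitrated.
7. **Rates and inheritance** (`mutation_rate`, `spontaneous_variants`,
   `inheritance_table`). Rates are quoted per site per tetraploid genome,
   i.e. the denominator is `genome_length × 4` — the convention under
   which both published worked examples (≈2.8×10⁻⁶ pre-existing,
   5.43×10⁻⁸ T0→T1) are recovered from their printed counts; the factor
   is a parameter. Allele inheritance uses raw evidence counts with no
   noise threshold by default (`min_count = 1`), matching tables that
   report single-clone observations; the threshold is exposed.

## The specificity score

Candidate sites carry the position-weighted specificity score
(`specificity_score`) on a 0–100 scale:

$$ S = 100 \prod_{p \in M} (1 - W_p) \times \frac{1}{\tfrac{19-\bar d}{19}\cdot 4 + 1} \times \frac{1}{n^2} $$

where $M$ is the set of mismatched protospacer positions, $n = |M|$,
$\bar d$ the mean distance between consecutive mismatches, and the last
two factors apply only for $n \ge 2$. Position 1 is the PAM-distal end;
the default weights $W$ are the experimentally derived per-position
penalties of the widely used mammalian-cell scoring scheme, which
penalizes seed (PAM-proximal) mismatches most. PAM bases are never
counted as mismatches — the mismatch budget is scoped to the 20-bp
protospacer. The *on-target* activity score used during guide design is
a proprietary web-tool quantity and is intentionally not re-implemented;
`find_candidate_guides` takes any user scorer and defaults to a
documented stub (constant 1.0) that leaves only the GC gate active,
flagging its output as a surrogate.

## What the simulator emulates

`simulate_study` builds a study in which every inference the pipeline
makes is checkable against truth labels:

* a two-chromosome i.i.d. genome (default 200 kb, GC 0.35 — AT-rich like
  a plant genome) standing in for the At/Dt subgenome pair, with one
  guide given duplicated intended loci on both chromosomes and one a
  single locus, mirroring the duplicated-target structure of an
  allotetraploid;
* a decoy ladder per guide — implanted near-matches at exactly
  k = 1…5 mismatches across the three PAM classes — plus whatever chance
  homology the random genome contributes;
* pre-existing variants identical in every sample; shared somaclonal
  variants drawn from a pool with each pool variant assigned to **at
  least two** regenerants; private somaclonal variants unique per
  regenerant. The ≥2 multiplicity is what makes "private" well defined:
  a shared variant observed in exactly one edited plant would be
  indistinguishable from a private one, and the observed negative/edited
  overlap fractions (tens of percent in real cohorts) emerge from the
  pool assignment;
* deletion-dominant edits (weights d1 0.40, d2 0.20, d3 0.05, i1 0.20,
  s 0.15 — 1–2-bp deletions are the commonest Cas9 outcome) placed at
  the cleavage side of the site, with the constraint that an edit's
  normalized representation stays inside its site's 23-bp interval;
* off-target edits at enumerated sites with probability
  `0.3 · logistic(1.5·(1 − mm))` in the mismatch count — a logistic
  decay making edits rare beyond 3 mismatches. Real per-site off-target
  rates are far lower (a handful of hits among thousands of sites); the
  desk-scale default is raised so a finite cohort contains a nonzero
  number of recoverable hits, and the law is fully user-overridable;
* T1 plants inherit their parent wholesale plus 30 new spontaneous
  mutations placed away from any site ± flank, so cross-generation
  isolation is exact by construction;
* caller annotations drawn from simple parametric families whose only
  meaningful property is which side of each hard-filter threshold they
  fall on. A configurable 5% of records per sample violates exactly one
  clause; passing records hold QUAL constant (100) because any
  continuous QUAL spread would make roughly half of the clean records
  fail their own sample-mean threshold, conflating the filter test.
  Truth records carry the violated clause.

Not emulated: read-level data (no FASTQ/BAM, so no allele fractions or
depth structure beyond the DP annotation), polyploid phasing and
homoeologous cross-mapping, linked variation, sequencing error, and the
GATK ∩ SAMtools caller-consensus step (with one VCF per sample the
consensus is represented only by the hard filters). Passing recovery
tests therefore demonstrates the correctness of the *cohort logic*, not
robustness to caller noise or mapping artefacts in real data.

## Numerical and convention choices

* Coordinates are 1-based closed intervals internally — the
  IRanges/Bioconductor convention — with BED's 0-based half-open form
  produced only at the file boundary and VCF staying 1-based. Using the
  ecosystem's native convention avoids a translation layer in every
  GenomicRanges call.
* Mismatch positions are indexed 1 = PAM-distal, 20 = PAM-proximal, and
  the site interval always spans protospacer+PAM (23 bp).
* Soft-masked bases are uppercased on load; N never matches any base and
  N-containing windows are not sites.
* In re-assessment, a relocated site's 23-mer is re-extracted anchored at
  the mapped position of its 5′-most reference coordinate; intervals whose
  anchor was deleted are reported `destroyed_site` with the personalized
  fields undefined. A PAM change between two *valid* classes (e.g.
  NGG→NGA) sets both `pam_destroyed` and `pam_created`.
* The published "61 altered sites" tally is ambiguous between variants
  and affected sites; the summary table counts affected sites, while each
  re-assessment record carries its causal variant keys so the variant
  tally is also available.
* Simulation determinism: every entry point seeds its own RNG stream
  from `params$seed` (with small fixed offsets), so genomes, cohorts and
  layouts reproduce record-for-record under one integer.

## Problem sizes used in validation

The test-suite and the acceptance script run the simulator at a 200-kb,
two-chromosome genome with 3 WT / 3 negative / 4 edited / 2 T1 samples
(200 pre-existing, ~60 shared + 40 private somaclonal per regenerant,
30 spontaneous per T1), plus a 60-kb variant for fast unit checks, and
verify the enumerator against the brute-force oracle on 100 random
instances of 1.2–10-kb genomes across all mismatch budgets and PAM-class
subsets. These sizes exercise every code path (duplicated loci, both
strands, all PAM classes, all edit types, filter violations of every
clause) while keeping a full run in tens of seconds. Published worked
examples (the two rates, the ratio-table cells, the novel-site tally and
the inheritance table) are pinned at printed precision.

## Known limitations

* The enumerator is a dense scan — linear in genome length per guide. It
  is sized for desk-scale validation and bacterial-to-small-plant
  genomes; Gb-scale enumeration calls for an indexed search engine,
  whose output can be fed into the rest of the pipeline unchanged.
* DNA/RNA-bulge off-targets are out of scope; mismatch counting is
  substitution-only.
* Personalization is haploid: one variant-applied sequence per
  chromosome, no heterozygous branching.
* `classify_allele` codes single contiguous events (`d<k>`, `i<k>`,
  `s<k>`); compound alleles are reported `complex` rather than decomposed.
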