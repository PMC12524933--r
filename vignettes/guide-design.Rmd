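---
title: "Designing CRISPRi guides with crisprikit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CRISPRi guides with crisprikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprikit)
```

## The model

CRISPR interference represses a gene by placing a catalytically dead
Cas9, addressed by a single-guide RNA, on the DNA. Within an open
reading frame the complex acts as a roadblock to transcript elongation,
which is only effective when the sgRNA base-pairs with the non-template
(sense) strand of the gene. `crisprikit` encodes that mechanism as a
purely geometric search problem:

* For a feature on genomic strand $s$, the protospacer and its
  5′-NGG-3′ PAM must lie on the strand opposite $s$. The feature's
  sense sequence is therefore scanned for `CCN` (the reverse complement
  of the PAM) at offset $i$; the spacer is the reverse complement of the
  `spacer_len` nucleotides that follow, and $d_5 = i$ records the
  distance from the 5′ (start-codon) end of the feature.
* Binding is modelled by the contiguous run of matched bases counted
  from the PAM-proximal end of the spacer. A site is bound when the run
  reaches `min_pairing_run` (12 nt); this subsumes the stricter
  requirement of perfect pairing over the 7 PAM-proximal nucleotides,
  since any mismatch inside the first 7 truncates the run below 12.
* Specificity is screened by exhaustive exact matching of the
  *specificity pattern* — the 12-nt PAM-proximal seed followed by the
  PAM with its N left as a wildcard, i.e. 14 informative nucleotides —
  over both strands of every replicon. A guide whose pattern matches
  more than one locus (the self site counts) is discarded. This is an
  exact re-implementation of the published screening criterion rather
  than a heuristic aligner: on bacterial genome scales, exhaustive
  matching is cheap and has no sensitivity parameters.

The assumptions worth stating: binding is treated as all-or-none at the
pattern level (no mismatch-weighted off-target score); PAM-distal
mismatches beyond the pairing run are ignored; and no on-target
efficiency model beyond the seed GC flag is attempted.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `spacer_len` | 20 | nt | standard S. pyogenes sgRNA base-pairing region |
| `seed_len` | 12 | nt | PAM-proximal seed used for the uniqueness pattern |
| `exact_core_len` | 7 | nt | PAM-proximal stretch requiring perfect pairing |
| `min_pairing_run` | 12 | nt | minimum contiguous PAM-proximal pairing for binding |
| `pam` | `NGG` | motif | S. pyogenes dCas9; N is a wildcard |
| `gc_warn_below` | 0.40 | fraction | see below |
| `require_unique` | `TRUE` | — | discard multi-site guides |
| `strand_rule` | `non_template` | — | elongation-block mechanism |

The GC warning threshold sits deliberately between the observed weak
regime (a ~33% GC seed silences noticeably less efficiently) and the
observed effective range (42–58%). It is a warning, not a filter,
because weak silencing can still be the desired outcome; 0.40 cleanly
separates the two regimes for 12-nt seeds (4/12 ≈ 33% flagged, 5/12 ≈
42% not).

## Conventions and numerical choices

* **Coordinates** are 0-based half-open internally and in BED output;
  GFF3 I/O converts to and from 1-based inclusive at the file boundary
  only. The round trip is tested to be the identity.
* **dist5** measures from the feature's 5′ end to the 5′-most base of
  the protospacer in feature orientation. Any fixed monotone convention
  gives the same ranking; this one makes `dist5 = 0` mean "protospacer
  abuts the start codon".
* **Ranking ties** are broken deterministically by (record, coordinate,
  spacer lexicographic) so that outputs are byte-reproducible.
* **The uniqueness pattern** places the wildcard at the PAM's first
  position (`seed + NGG`). The alternative reading — GG immediately
  followed by the wildcard (`GGN`) — would shift the pattern by one
  base; we follow the 5′-NGG-3′ statement of the PAM, and the PAM motif
  is configurable for users with the opposite convention.
* **Whole-feature containment**: both protospacer and PAM must lie
  inside the annotated feature (search is "within the coding
  sequence"), so the minimum targetable feature length is
  `spacer_len + 3` = 23 nt. A 66-nt sRNA is comfortably above this
  bound; a 20-nt one is untargetable by geometry.
* **Circular replicons**: the binding-site scan wraps the origin only
  when a record is flagged circular, by extending the subject with the
  first `pattern − 1` bases and keeping matches that start before the
  origin. Features themselves may not wrap; linear is the conservative
  default.
* **N handling**: ambiguity codes other than N collapse to N on input
  (with a warning). Candidates containing N are dropped, and N in the
  genome never satisfies any pattern position, wildcard included.
* **Degenerate inputs**: features shorter than 23 nt yield an empty
  candidate list with a note, not an error; an empty feature set yields
  a 0/0 census.

## Escape allele design

To complement a silenced gene, its coding sequence is recoded
synonymously at the guide's footprint so that the complementing copy is
no longer a target. Two escape routes exist and are treated as
alternatives: destroying at least `min_pairing_run`-compatible pairing
inside the seed, or destroying the PAM's GG. The enumeration considers
synonymous substitutions at codons overlapping the seed or the PAM
(when the PAM spans a codon boundary, both codons are considered),
bounded at `max_codon_changes` codons per allele (default 2). The bound
is a design choice: recoding two codons in the PAM-proximal core is the
robust recommendation, single-codon escapes are retained for the
`min_codon_changes = 1` mode (a single proline-codon change can fully
abolish silencing), and enumerating three-plus-codon combinations adds
combinatorial volume without design value. Start and stop codons are
never mutated. No codon-usage or mRNA-structure model is applied — an
allele introducing a rare codon is emitted, not filtered.

`predicted_strength` is a coarse two-level label ("full" when at least
two seed codons change, the PAM is disrupted, or any change falls in
the 7-nt core; otherwise "partial"). Partial escapes are a real
phenomenon — a single PAM-distal valine-codon change restored only
about 70% of growth in the motivating system — but no quantitative
fitting target exists, so the package deliberately does not predict a
number.

Every emitted allele is verified at construction time: the mutant CDS
must translate (bacterial table 11, initiator translated per table) to
exactly the original protein, and `verify_escape()` must confirm that
the re-extracted protospacer instance fails the pairing rule or has
lost its PAM.

## Operon scope and censuses

Because the block is polar, `knockdown_scope()` reports the target plus
all co-operonic genes downstream in transcription order as silenced,
and upstream members as unaffected. Operon structure must be provided
in the annotation (`operon_id`/`operon_index` attributes); the package
does not infer operons from intergenic distances.

The targetability census answers "which of these features can be
targeted at all under the PAM constraint": a feature is targetable when
at least one candidate exists. The genome-wide uniqueness filter is
*not* applied by default — PAM availability, not uniqueness, is the
stated limiting factor for short features — but `apply_uniqueness =
TRUE` adds it, and the monotonicity (uniqueness can only shrink the
census) is property-tested. For sRNAs the non-template rule is applied
relative to the sRNA's own transcription direction, exactly as for a
CDS.

## The fixture generator

`generate_fixture()` builds the synthetic study system used throughout
the tests: background sequence at 36% GC (a low-GC firmicute-like
composition), CDS features assembled from non-stop codons, a planted
proline codon (`CCN`) wherever a candidate site is requested, sRNAs
with or without planted sites, and optional extra genomic copies of a
planted candidate's seed+PAM instance on alternating strands. Feature
sense sequences are generated free of the `CC` dinucleotide, so the
planted sites are provably the only candidates and the truth table
(candidate offsets, off-target counts, censuses) is exact by
construction; an internal scan re-verifies every expectation and the
generator resamples (bounded at 1,000 attempts) on the rare background
collision. Generation is deterministic for a given seed, uses a local
RNG scope that never perturbs the caller's random stream, and is tested
to be byte-identical across runs.

What the generator does *not* emulate: real codon-usage bias,
oligonucleotide composition, repeat structure, or the density of
near-miss seed matches found in a real genome. Passing the planted-truth
suite therefore demonstrates correctness of the scanning, counting and
census logic — not that any particular real genome yields a particular
census. Real-genome censuses are one `read_fasta()`/`read_gff3()` call
away for users with an annotated genome in hand.

## Problem sizes in the test suite

The property suites run on: 100 random genomes of 0.5–10 kb for the
brute-force equivalence of enumeration and binding-site counting (with
a naive position-loop oracle, plus circular records every fifth
genome); 1,000 random strings for the reverse-complement involution;
exhaustive 20-position single-mismatch sweeps of the pairing rule;
full single/double-codon escape enumerations against a nested-loop
oracle on 30-codon CDSs; and the 15-feature demonstration fixture for
end-to-end planted-truth, strand-symmetry and determinism checks. These
sizes keep the whole suite in the low minutes on one CPU while leaving
the oracles exhaustive at their scale.

## Known limitations

* No mismatch-tolerant off-target scoring (CFD-like models) — the
  screen is exact on 14 informative nucleotides, mirroring the
  discard-if-multi-site criterion it implements.
* No promoter-region targeting rules; designs are within annotated
  features only.
* No on-target efficiency prediction beyond the seed-GC flag.
* The sgRNA scaffold is treated as an opaque user-supplied string; no
  scaffold or vector-overlap sequences are bundled, since these are
  properties of the user's backbone.
* Operon structure is trusted as annotated; mixed-strand or
  non-consecutive operon indices are rejected rather than repaired.
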