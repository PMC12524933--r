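# crisprikit

CRISPRi guide design for bacterial genomes.

CRISPR interference silences a gene by parking a nuclease-dead Cas9
(dCas9), addressed by a single-guide RNA (sgRNA), on the DNA so that RNA
polymerase cannot elongate through it. The method needs no recombination
and is inducible, which makes it the tool of choice for studying
**essential genes** — such as the ribosome-associated endoribonuclease
gene *ybeY* in *Lactococcus lactis* — that cannot simply be deleted.
`crisprikit` implements the computational half of such an experiment for
microbiologists: picking the guides, checking their specificity,
predicting what else in the operon gets silenced, and producing the
cloning oligos.

## The design rules

For an ORF target with *S. pyogenes* dCas9, effective silencing requires:

* the sgRNA base-pairs with the **non-template (sense) strand**, so the
  protospacer and its **5′-NGG-3′ PAM** lie on the template strand —
  operationally, the sense sequence is scanned for `CCN` and the 20-nt
  spacer is the reverse complement of the following window;
* a contiguous PAM-proximal pairing run of at least **12 bp**, with
  perfect complementarity over the **7 nt** next to the PAM;
* genome-wide **uniqueness** of the specificity region — the 12-nt
  PAM-proximal *seed* plus the GG of the PAM, i.e. 14 informative
  nucleotides. Candidates matching more than one locus (on either strand
  of any replicon) are discarded;
* preference for sites **close to the 5′ end** of the coding sequence
  (ranking key `dist5`), because a roadblock early in the ORF truncates
  the most transcript;
* seeds below **40% GC** are flagged: low-GC seeds (~33%) still silence,
  but measurably more weakly than seeds in the 42–58% range.

Because the block is polar, silencing a gene also represses everything
downstream in its operon (`knockdown_scope()`), and because short
features rarely contain a usable `protospacer + PAM` (≥ 23 nt plus a
PAM on the right strand), only a minority of small RNAs are targetable
at all (`targetability_census()`). To complement a silenced gene without
re-targeting the complementing copy, `design_escape_alleles()` recodes
the target site with synonymous codons (two codons in the PAM-proximal
core recommended; single-codon escapes are supported) and
`verify_escape()` re-applies the pairing rule to prove the guide no
longer binds. Finally `make_guide_swap_oligos()` emits the two
complementary 50-nt primers (15-nt vector overlap + 20-nt spacer + 15-nt
vector overlap) used to swap a new spacer into a linearized sgRNA vector
by fusion cloning.

## Worked example

Everything below runs on a synthetic genome built by the package's own
deterministic fixture generator (no downloads needed):

```r
library(crisprikit)

fx  <- generate_fixture(demo_fixture_spec(seed = 42))
des <- design_guides(fx$features, fx$genome, targets = "opA1")
des$guides[, c("feature_id","spacer","pam","dist5","seed_gc","offtarget_count","rank")]
#>   feature_id               spacer pam dist5   seed_gc offtarget_count rank
#> 1       opA1 ACGTGACTATGATTCCCGCG CGG    30 0.5833333               1    1
des$discarded[, c("feature_id","dist5","offtarget_count")]
#>   feature_id dist5 offtarget_count
#> 2       opA1   120               3
```

The candidate 30 nt from the start codon is unique in the genome (its
binding-site count of 1 is its own locus) and becomes rank 1; the
candidate at 120 nt matches three loci — the fixture plants two extra
copies of its seed+PAM — and is discarded. The polar footprint and the
sRNA census:

```r
knockdown_scope("opA1", fx$features)
#> <knockdown_scope> opA1 (operon opA)
#>   silenced (polar): opA1 -> opA2 -> opA3
#>   unaffected upstream: (none)
targetability_census(fx$features[fx$features$ftype == "sRNA", ], fx$genome)
#> <census_result> 6 of 10 features targetable
```

Escape alleles for the rank-1 guide (two synonymous codon changes in the
seed; the protein is untouched), and the cloning oligos:

```r
f   <- fx$features[fx$features$id == "opA1", ]
cds <- feature_seq(f, fx$genome)
al  <- design_escape_alleles(f, des$guides[1, ], cds, min_codon_changes = 2)
al[1, c("changed_codons","nt_changes_in_seed","nt_changes_in_core7","predicted_strength")]
#>          changed_codons nt_changes_in_seed nt_changes_in_core7 predicted_strength
#> 1 11:CGC>AGA;12:GGG>GGA                  3                   3               full

make_guide_swap_oligos(des$guides$spacer[1], "GATTCGTGCTCTTTT", "GTTTTAGAGCTAGAA")
#> <oligo_pair>
#>   fwd: GATTCGTGCTCTTTTACGTGACTATGATTCCCGCGGTTTTAGAGCTAGAA
#>   rev: TTCTAGCTCTAAAACCGCGGGAATCATAGTCACGTAAAAGAGCACGAATC
```

Both oligos are 50 nt and mutual reverse complements; positions 16–35 of
the forward oligo are the spacer.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli","crisprikit.R",package="crisprikit"))')
Rscript $CLI fixture --out fx --seed 3
Rscript $CLI design  --genome fx/fixture.fasta --annotation fx/fixture.gff3 --out out
Rscript $CLI census  --genome fx/fixture.fasta --annotation fx/fixture.gff3 --out outc
```

Subcommands `design`, `census`, `escape`, `oligos`, `fixture`; flags
override an optional `--config` YAML. Exit codes: 0 success, 2 invalid
input, 3 empty result, 4 I/O failure.

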