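---
title: "Assigning homoeallelic base identities in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning homoeallelic base identities in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeallele)
```

## The problem

An allopolyploid genome carries two or more homeologous subgenomes donated
by distinct diploid progenitors. Because the subgenomes are closely
related, a short sequencing read usually aligns equally well to either
copy, and at a homeolog-specific polymorphism (HSP) -- a reference
position where the subgenomes carry different bases -- the pileup of
polyploid reads mixes the homoeallelic variants. The task this package
addresses is to decide, for every HSP position and every subgenome, which
base that subgenome carries, using (i) the polyploid read alignments
against a transcriptomic reference and (ii) lists of single-base
substitutions (SBSs) that describe how each available diploid progenitor
differs from that reference. The method tolerates the absence of
sequencing data for one progenitor, which matters in practice: several
well-studied allopolyploids have an unsequenced or extinct donor.

## The procedure

Reads are first filtered: mapping quality must exceed a threshold
(default: MAPQ <= 20 removed), read pairs with a single aligned mate are
dropped, and so are pairs whose mates fall in different genes of the
concatenated reference. Both mates of a surviving pair are fused into one
*fragment*; where the mates overlap and disagree, the position is treated
as uncovered in that fragment (a conservative choice -- the evidence is
contradictory). All read-support counting downstream is fragment-level,
so a pair never contributes twice at a position.

The core algorithm then proceeds in six steps per gene:

1. **Base patterns.** Each fragment is reduced to its ordered
   (position, base) pairs over the gene's validated HSP positions.
   Identical patterns collapse, keeping a support count.
2. **Noise removal.** For each pair of *consecutive* HSP positions, the
   support of every base combination is tallied over patterns covering
   both positions; patterns containing a combination below 5% of the
   tally are removed, as are patterns embedded in a larger pattern
   (their support is discarded, not transferred -- they add no
   information beyond the container).
3. **Iterative merging** (on by default exactly when a diploid is
   missing). Two patterns merge when they agree at every shared position
   and share at least `min_overlap` positions; the pair with the largest
   overlap merges first and the process repeats. Longer patterns span
   more HSPs and are therefore much harder to misassign, which is what
   rescues accuracy when one progenitor has no data.
4. **Pattern assignment.** A pattern's identity with a diploid is the
   percentage of its positions, among those where the diploid profile has
   a concrete base, at which it matches. Patterns at or above 50%
   identity are assigned to that subgenome (several subgenomes are
   allowed; the election arbitrates). A pattern assigned nowhere goes to
   the missing subgenome, if one exists -- every fragment must originate
   from *some* subgenome.
5. **Base election.** Per position and subgenome, the base of the
   best-scoring assigned pattern wins (maximum mode), or the base with
   the largest summed score over patterns containing it (additive mode);
   exact ties give no call. Patterns conflicting with an elected base of
   their subgenome are removed, still-open positions are re-elected (a
   removal can break an earlier tie), and passes repeat until no more
   bases can be assigned; elected bases are never retracted.
6. **Finalization.** Since every observed base at an HSP belongs to some
   subgenome, a position with exactly one unassigned base and exactly one
   uncalled subgenome is completed by elimination. Leftover patterns
   (never assigned, or removed in step 5) are re-scored against the
   assigned bases themselves and can fill remaining gaps. This step can
   mistake allelic (within-subgenome) variation for homeologous variation
   and is switchable off for heterozygous species.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `hsp_min_frac` | 0.05 | minimum read fraction for a valid HSP base |
| `sbs_min_frac` | 0.30 | minimum read fraction supporting a diploid SBS |
| `min_diploid_coverage` | 3 reads | below this a diploid position is low-coverage (`<`) |
| `ambiguous_min_frac` | 0.20 | second base above this makes a diploid position ambiguous (`*`) |
| `basepair_min_frac` | 0.05 | rare base-pair filter of step 2 |
| `identity_min` | 0.50 | minimum diploid identity for pattern assignment |
| `mode` | `max` | base election mode (`max`/`additive`) |
| `merge` | auto | pattern merging; on iff a diploid is missing |
| `min_overlap` | 1 | minimum shared positions for a merge |
| `mapq_min` | 20 | reads with MAPQ at or below are removed |
| `gap_length` | 200 | N spacer between concatenated unigenes |

`min_overlap = 1` is sufficient for tetraploids, where the two subgenomes
differ at every true HSP, so same-gene patterns from different subgenomes
always conflict somewhere and chimeric merges cannot chain. In higher
ploidies two subgenomes can share the base at an HSP; raising
`min_overlap` makes merging more conservative there.

## Numerical and design choices

Several details are deliberate choices where the method's description is
open; they are fixed here and tested:

* **Threshold boundaries.** "At least 5%" (and 30%, 50%) is implemented
  as `count + 1e-9 >= frac * total`. The epsilon only compensates binary
  floating-point representation (0.05 × 100 is slightly above 5 in
  doubles); for integer counts it is exactly the rational comparison, so
  5 reads of 100 *is* a valid 5% base.
* **Validation denominators** use reads with A/C/G/T calls at the
  position (fragment-level), the same unit as pattern support.
* **Merge tie-breaks.** Among pairs with the largest overlap, the merged
  candidate with the smallest leftmost position wins, then the
  lexicographically smallest base string. This makes runs byte-identical.
* **Election score of the missing subgenome.** Its patterns have no
  diploid identity, so the score is 100 minus the best identity with any
  present diploid ("least like any known progenitor"); if no identity is
  defined at all, read support is used as the rank. Ties still yield no
  call.
* **Ambiguity code.** A diploid position is ambiguous (`*`) when two or
  more bases each reach 20% of its reads, mirroring the exclusion of
  heterozygous diploid calls during SBS ingestion; ambiguous positions
  are non-informative for identity.
* **No-coverage fallback.** Without a diploid coverage table, a non-SBS
  position takes the reference base: an SBS list is defined relative to
  the reference, so absence of a record is itself the claim of identity
  with it.
* **Finalization only adds.** The recheck feeds leftover patterns into
  the election for still-empty cells; existing calls are never retracted,
  so the loop is monotone and terminates. Iteration caps (100) guard both
  loops; each election pass either stabilizes or removes a pattern, so
  the caps are unreachable on sane inputs.
* **Reference construction.** One N spacer follows *every* concatenated
  sequence (n gaps for n sequences). The alternative (n-1 internal gaps)
  is arithmetically incompatible with published separator totals for
  references built this way, so the n-gap convention was adopted.

## The simulator

`simulate_allopolyploid()` provides the ground-truth substrate for every
end-to-end test. It draws ancestral genes uniformly over ACGT, mutates
each site in each subgenome with probability `hsp_rate` (default 0.01, a
typical homeologous divergence for young allopolyploids), diverges one
diploid per subgenome at `diploid_divergence` (default 0.003), and
samples 2 × 100 bp read pairs at 30× per subgenome with a 0.2% uniform
base error. Reads are emitted as pre-aligned SAM records at their true
coordinates, so the alignment stage -- explicitly outside this package's
scope -- is bypassed without external binaries. The candidate HSP and SBS
lists handed to the pipeline are *called from the simulated pileups* with
the same naive threshold rules the validation step uses, not copied from
truth, so ingestion and validation are exercised too. The emulated HSP
caller additionally requires two supporting reads per allele, standing in
for the low-quality-variant filter every real calling pipeline applies;
without it, a single sequencing error at a shallow position (depth near
the calling minimum of 3) would satisfy the 5% rule and flood the
candidate list with singleton-error alleles.

What the simulator does **not** emulate: expression-level variation
between genes and homeologs (coverage is uniform), silenced homeologs,
gene conversion and homeologous exchange, indels, intron structure,
allelic heterozygosity within a subgenome, and alignment artifacts
(mismapping between paralogs). Passing tests therefore demonstrate the
correctness and stability of the assignment machinery under the stated
generative model; on real data, silenced or converted loci will still
produce confidently wrong calls, exactly as they do for any
diploid-similarity method.

Problem sizes: the bundled performance checks run 200 genes × 1 kb for
the tetraploid missing-diploid condition and 150 genes × 1 kb × 3
subgenomes for the hexaploid condition; unit and property tests use 3-20
genes. These sizes give a few thousand HSPs per run, enough for stable
accuracy estimates at desk scale.

## Worked example

```{r worked}
fx <- make_worked_fixture()
res <- run_pipeline(fx$fragments, fx$hsps, fx$genes, fx$sbs,
                    dip_coverage = fx$dip_coverage)
res
tidy(res)[, c("pos", "subgenome", "diploid_code", "assigned_base")]
glance(res)
```

The fixture's position 25 is the interesting one: subgenome `s2`'s
diploid has only two reads there (code `<`), its single-position pattern
has no informative identity, and the base C is placed only by the
elimination rule of step 6. Running with
`core_config(finalize = FALSE)` leaves that position incomplete.

## Limitations

Within-subgenome heterozygosity is not modeled; homeolog silencing, gene
conversion and homeologous exchange bias calls at affected loci; indel
HSPs and structural variants are out of scope; references are
transcriptomic (concatenated unigenes), not genomic with introns. The
comparison utilities report shared-position/shared-base counts only --
significance testing is left to downstream tools.
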