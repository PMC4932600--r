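# homeallele

Genome-wide assignment of **homoeallelic base identities** in
allopolyploids from NGS read alignments and diploid-progenitor
substitution lists — including when data for one diploid progenitor is
missing entirely.

## The problem

An allopolyploid combines two or more homeologous subgenomes. At a
**homeolog-specific polymorphism (HSP)** the subgenomes carry different
bases, and the polyploid's RNA-seq pileup at that reference position is a
mixture of homoealleles. `homeallele` decides, for every HSP position and
every subgenome *s*, which base *s* carries, given:

* position-sorted SAM/BAM alignments of polyploid reads against a
  transcriptomic reference of concatenated unigenes,
* a VCF of candidate HSPs in the polyploid,
* one VCF of single-base substitutions (SBSs) per available diploid
  progenitor (up to ten), and
* optionally, per-base coverage tables for validation and a GFF3 of gene
  intervals.

The method: read pairs are reduced to **base patterns** — ordered
(position, base) pairs over the HSP sites they cover. After a noise
filter (base pairs at consecutive HSPs supported by < 5% of reads) and
removal of embedded patterns, overlapping compatible patterns can be
iteratively merged (longest overlap first). Each pattern's **percentage
identity** with diploid *d* is

&nbsp;&nbsp;&nbsp;&nbsp;*I(P, d)* = 100 · |{ i : P(i) = d(i), d(i) ∈ {A,C,G,T} }| / |{ i : d(i) ∈ {A,C,G,T} }|

and a pattern is assigned to every subgenome with *I* ≥ 50%. A pattern
assigned nowhere goes to the **missing** subgenome, if one was declared —
it must come from somewhere. A per-position election (maximum or additive
over pattern scores, ties → no call) then fixes one base per subgenome,
removes conflicting patterns, and iterates; a finalization step completes
positions where only one base and one subgenome remain open and rechecks
leftover patterns against the calls themselves.

## Worked example

The package ships a hand-traceable fixture: one 30 bp gene, HSPs at
positions 5, 15 and 25, six fragments, two subgenomes, with diploid `s2`
having SBSs at positions 5 and 15 but only two reads at position 25.

```r
library(homeallele)
fx  <- make_worked_fixture()
res <- run_pipeline(fx$fragments, fx$hsps, fx$genes, fx$sbs,
                    dip_coverage = fx$dip_coverage)
res
#> <homeallele_result>
#>   subgenomes: s1, s2
#>   HSP positions: 3 (reported: 3, fully characterized: 3)
#>   base patterns used: 4
tidy(res)[, c("pos", "subgenome", "diploid_code", "assigned_base")]
#>   pos subgenome diploid_code assigned_base
#> 1   5        s1            A             A
#> 2   5        s2            G             G
#> 3  15        s1            C             C
#> 4  15        s2            T             T
#> 5  25        s1            G             G
#> 6  25        s2            <             C
```

Position 25 shows the finalization step at work: diploid `s2` is
low-coverage there (code `<`), so no pattern reaches it by diploid
identity — the base C is placed by elimination, because the only other
observed base (G) already belongs to `s1`.

`glance(res)` gives the one-row run summary
(`n_hsp_positions = 3, n_fully_characterized = 3, n_assignments = 6, ...`),
and `autoplot(res)` plots assigned positions per subgenome.

## Command line

A thin wrapper over the same functions:

```sh
homeallele seq2ref  --fasta unigenes.fa --gap 200 --out ref
homeallele coverage --bam poly.bam --gff ref.gff3 --out poly_cov.tsv
homeallele run --bam poly.bam --hsp hsp.vcf --gff ref.gff3 \
    --sbs A=sbs_A.vcf,B=sbs_B.vcf --missing C \
    --poly-cov poly_cov.tsv --out calls/
homeallele simulate --seed 42 --out sim/
homeallele compare --a s1=a/s1.tab,s2=a/s2.tab --b s1=b/s1.tab,s2=b/s2.tab
```

Outputs are one VCF and/or tab file per subgenome; the tab columns are
sequence, position, reference base, diploid code (`0` no coverage, `<`
low coverage, `*` ambiguous, `?` missing diploid), assigned base, and a
yes/no fully-characterized flag.

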