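# methylRM

Bacterial restriction–modification (RM) systems pair a DNA methyltransferase,
which marks the cell's own genome at a specific recognition motif, with a
restriction endonuclease that cleaves unmarked (foreign) DNA. SMRT sequencing
reads the methylome directly — per-motif detection fractions over all genomic
occurrences — which makes it possible to connect observed methylation motifs
back to the genes that produce them. `methylRM` implements that inference as a
reusable pipeline for staphylococcal-style genomes:

- **Gene role classification (types I–IV).** Ordered keyword rules over CDS
  annotation text, refined by gene-length rules (a fused
  methyltransferase–endonuclease of a type IIG system runs > 4 kb; a type III
  *res* gene is 2.7–3 kb and sits next to a *mod* methyltransferase), with
  role-specific length floors marking truncated genes.
- **Operon reconstruction and topology labels**, including the four-gene
  *hsdRSMS* arrangement in which two specificity subunits (*hsdS*_short,
  *hsdS*_long) flank the methyltransferase and the 3′ end of *hsdM* overlaps
  the 5′ end of *hsdS*_long by 8 bp; Shine-Dalgarno (AGGAGG) and σ70 promoter
  (TTGACA–N16–19–TATAAT) detection supports the single-promoter reading of the
  operon.
- **Degenerate motif algebra.** IUPAC reverse complement, bipartite
  decomposition (half-site / N-spacer / half-site, e.g. TCA-N6-CTC),
  palindromy, duplex-aware genome scanning, and the modification-fraction
  statistic `fraction = nDetected / nGenome` with half-up rounding as printed
  in SMRT motif reports.
- **Motif-to-enzyme assignment** by cross-strain presence/absence concordance
  of gene families (single-linkage clustering at 90% identity) against motif
  presence, plus lookup in user-supplied known-motif tables.
- **Type I family classification (IA–IE)** by global-alignment percent
  identity (BLOSUM62, affine gaps, end gaps counted) against per-family
  reference proteins, with the consensus verdict thresholds — members of one
  family share ≳ 70% identity, members of different families < 30% — and
  neighbor-joining trees on `d = 1 − identity/100`.
- **HsdS architecture.** Per-column conservation profiles of specificity
  subunit alignments, segmentation into conserved regions and target
  recognition domains (N-CR / TRD1 / cCR / TRD2 / C-CR), and detection of
  tandem tetrapeptide repeats and short gapped repeats (e.g. 2× LEEQK
  separated by 3 residues).
- **A fully seeded synthetic-data generator** that plants operons, motifs,
  regulatory signals, alignments and cross-strain linkage with
  machine-readable ground truth, so the entire pipeline runs and is testable
  with no network access.

The package also ships a curated inventory of RM genes and methylation motifs
across 14 *Staphylococcus xylosus* strains as a text fixture
(`inst/extdata/table1_rm_inventory.tsv`, checksummed).

## Worked example

```r
library(methylRM)

# strain-level inventory from the packaged fixture
inv <- run_inventory(fixture = TRUE)
inv$summary[c("n_strains", "complete_type_I", "type_IIG")]
#> $n_strains
#> [1] 14
#> $complete_type_I
#> [1] 7
#> $type_IIG
#> [1] 3
```

Fourteen strains; seven carry a complete type I system (non-truncated *hsdR*,
*hsdM* and at least one *hsdS* in one operon), three carry a fused type IIG
enzyme.

```r
# motif algebra on an observed type I motif
bipartite_decompose("TCANNNNNNCTC")
#> <BipartiteDecomposition> TCA-N6-CTC
reverse_complement("TCANNNNNNCTC")
#> [1] "GAGNNNNNNTGA"
modification_fraction(1118, 1192)   # detected / genomic occurrences
#> [1] 0.94

# a synthetic strain with a planted hsdRSMS plasmid operon
syn <- generate_strain(strain_config("hsdRSMS"), seed = 42)
rec <- syn$records[[1]]
ops <- reconstruct_operons(classify_gene_table(rec$genes), rec$replicon_id)
ops[[1]]
#> <Operon> syn1_hsdRSMS [hsdRSMS] strand +: hsdR-hsdS-hsdM-hsdS (complete)
ops[[1]]$overlaps$overlap_bp   # hsdM/hsdS_long translational coupling
#> [1] 8
```

A thin command-line front end over the same functions is installed at
`system.file("scripts", "methylRM", package = "methylRM")` with subcommands
`inventory`, `families`, `hsds`, `match`, `simulate` and `fixture`.

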