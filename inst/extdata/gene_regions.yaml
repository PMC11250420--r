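# Drug-target gene windows for cis-instrument selection.
# Coordinates are Ensembl gene-body bounds; edit freely — nothing in the
# package hard-codes them. flank_kb follows the study design: 500 kb around
# SLC5A1 (SGLT1) and 1000 kb around SLC5A2 (SGLT2).
regions:
  - gene: SLC5A1
    chrom: "22"
    start: 32439248
    end: 32509016
    flank_kb: 500
    genome_build: GRCh37
  - gene: SLC5A1
    chrom: "22"
    start: 32043032
    end: 32113025
    flank_kb: 500
    genome_build: GRCh38
  - gene: SLC5A2
    chrom: "16"
    start: 31494323
    end: 31502089
    flank_kb: 1000
    genome_build: GRCh37
  - gene: SLC5A2
    chrom: "16"
    start: 31483097
    end: 31490863
    flank_kb: 1000
    genome_build: GRCh38
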