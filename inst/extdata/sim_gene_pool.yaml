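pool_size: 2000
gene_length_bp: 2000
genes:
- gene_id: GNB1
  chrom: '1'
  q1: 15
  q2: 10
- gene_id: LOC102467217
  chrom: '5'
  q1: 7
  q2: 1
- gene_id: PDE5A
  chrom: '4'
  q1: 11
  q2: 1
- gene_id: C11orf48
  chrom: '11'
  q1: 2
  q2: 2
- gene_id: CTTNBP2NL
  chrom: '1'
  q1: 5
  q2: 2
- gene_id: PTCH1
  chrom: '9'
  q1: 12
  q2: 3
- gene_id: SLC25A25
  chrom: '9'
  q1: 4
  q2: 3
- gene_id: CCL15-CCL14
  chrom: '17'
  q1: 9
  q2: 4
- gene_id: CD164
  chrom: '6'
  q1: 7
  q2: 4
- gene_id: IGSF22
  chrom: '11'
  q1: 10
  q2: 5
- gene_id: CRBN
  chrom: '3'
  q1: 9
  q2: 5
- gene_id: VAMP1
  chrom: '12'
  q1: 5
  q2: 6
- gene_id: CLEC17A
  chrom: '19'
  q1: 7
  q2: 6
- gene_id: DMGDH
  chrom: '5'
  q1: 21
  q2: 7
- gene_id: LPA
  chrom: '6'
  q1: 24
  q2: 7
- gene_id: CD276
  chrom: '15'
  q1: 7
  q2: 8
- gene_id: MED13L
  chrom: '12'
  q1: 19
  q2: 8
- gene_id: KBTBD12
  chrom: '3'
  q1: 22
  q2: 9
- gene_id: HLA-DQB2
  chrom: '6'
  q1: 19
  q2: 9
- gene_id: GM2A
  chrom: '5'
  q1: 12
  q2: 10
- gene_id: LRRC63
  chrom: '13'
  q1: 20
  q2: 10
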