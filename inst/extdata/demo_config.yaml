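# Demo run: 200 ortholog pairs at 1% homolog divergence, 5% transfer,
# 10,000 reads per sample (about 50 reads per gene), error-free reads.
simulation:
  n_genes: 200
  cds_len_range: [600, 1800]
  divergence: 0.01
  mobile_down_frac: 0.10
  mobile_up_frac: 0.02
  mobile_bidir_frac: 0.03
  mobile_transfer_frac: 0.05
  read_len: 150
  depth: 10000
  error_rate: 0.0
  seed: 11
  species: [Csa, Cmo]
classifier:
  self_discard_max_mm: 3
  donor_accept_max_mm: 1
  min_diagnostic_snps: 2
  require_perfect_donor_homograft_match: true
  min_fpkm: 1.0
  min_replicates: 2
  min_reads_per_gene: 2
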