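# Example three-stage run: simulate inputs, screen the domain table,
# test TE enrichment. Paths under out_dir are produced by the simulate stage.
seed: 11
out_dir: pipeline_out
stages: [simulate, screen, enrich]
simulate:
  domains:
    n_proteins: 100
    planted_pairs:
      - multicopy_accession: IPR001810
        te_accession: IPR041426
        n_carriers: 20
        te_position_mode: nterm
  genome:
    n_genes: 50
    n_tes: 150
    n_pfams: 8
    n_focal_genes: 10
    lambda: 4
screen:
  domains: pipeline_out/simulate/domain_domains.tsv
  sets: pipeline_out/simulate/domain_sets.tsv
  taxonomy: pipeline_out/simulate/domain_taxonomy.tsv
enrich:
  genes: pipeline_out/simulate/genes.gff3
  tes: pipeline_out/simulate/tes.gff3
  pfam: pipeline_out/simulate/pfam_map.tsv
  lengths: pipeline_out/simulate/scaffold_lengths.tsv
  replicates: 200
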