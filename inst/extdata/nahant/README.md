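# Study data drop-in directory

The end-to-end acceptance tests look here for the original survey tables,
which are not redistributable with the package:

- `killing_matrix.tsv` — wide TSV killing matrix (first column host ids,
  header row phage ids, cells 0/1) for the assayed host panel.
- `phage_annotations.tsv` — TSV with header
  `phage_id  species_group  genus_group  morphotype  life_history`.
- `phage_genomes.fasta` — multi-FASTA of phage genomes (record id =
  phage_id; NCBI BioProject PRJNA328102).

Place the files here before `R CMD INSTALL` to activate those tests; without
them the corresponding test blocks report failure.
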