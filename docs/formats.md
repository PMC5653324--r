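# File formats

All tabular outputs are TSV with a header row; all FASTA is wrapped at 70
columns. `run_pipeline(..., out_dir = )` writes the files below and echoes
the configuration to `config.tsv` (parameter, value).

## Inputs

| file | format | columns / headers |
|---|---|---|
| strain CDS sets | FASTA | headers `strainID|cdsID` |
| reference panel | FASTA | headers `geneID|category|family` |
| subsystem table | TSV | `cds_id`, `strain_id`, `subsystem` |
| feature table | TSV | `strain`, `group`, `genome_size` (Mbp), `n_cds`, `gc_percent` |
| measurements | TSV | `strain_id`, `group`, `timepoint_h`, `value` |
| qPCR standards | TSV | `copies`, `cq` |

## Outputs

| file | columns |
|---|---|
| `clusters.tsv` | `ortholog_id`, `strain_id`, `cds_id` (one row per member) |
| `consensus.fasta` | one consensus per ortholog, headers `OGnnnn` |
| `pan_matrix.tsv` | `strain`, then one copy-number column per ortholog |
| `summary.tsv` | `metric` (total, core, strain_specific, exclusive_&lt;group&gt;), `value` |
| `sharing_histogram.tsv` | `n_strains`, `n_orthologs` |
| `panel_hits.tsv` | `ortholog_id`, `gene_id`, `category`, `family`, `identity`, `score`, `evalue`, `accepted`, `best` |
| `panel_presence.tsv` | `strain`, then one 0/1 column per panel gene |
| `copy_number_comparison.tsv` | `gene_id`, `category`, `mean_<group>` x2, `t`, `df`, `p_value`, `significant` |
| `enrichment.tsv` | `subsystem`, `n_<group>`/`other_<group>` x2 (the 2x2 cells), `odds_ratio`, `p_value`, `significant` |
| `presence_tree.nwk`, `mlst_tree.nwk` | Newick; branch lengths; integer bootstrap percentages as internal-node labels |
| `feature_groups.tsv` | `group`, `n`, `<feature>_mean`/`<feature>_sd` per feature |
| `feature_tests.tsv` | `feature`, `t`, `df`, `p_value` (two-sided Welch) |
| `measurement_summary.tsv` | `group`, `timepoint_h`, `n`, `mean`, `sd` (assay units) |
| `fold_changes.tsv` | `strain_id`, `group`, `fold_change` (48 h / 24 h) |

Units are carried in column names or this table: genome sizes in Mbp, dye
masses in μg, copies as genome equivalents per reaction.
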