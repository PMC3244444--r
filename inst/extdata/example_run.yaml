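# Example configuration for run_full_analysis(). Paths are relative to the
# working directory; generate the fixture bundle first (analysis/01_fixtures.R
# or make_fixture_set("results/fixtures", seed = 1)).
alignment: results/fixtures/clade_positive.fasta
gene: prm_fixture
site_tree: results/fixtures/clade_tree.nwk
clade_tree: results/fixtures/clade_tree.nwk
foreground: [FG1, FG2, FG3, FG4, FG5, FG6, FG7, FG8]
traits: results/fixtures/traits.tsv
allometry:
  a: 0.031
  b: 0.77
# codon count of the cleaved N-terminal domain; omit for single-domain genes
prm2_boundary: 120
# 0-based residue positions of configured cleavage sites on the reference row
cleavage_sites: [2, 5, 8, 11, 14, 17, 20, 23, 26, 29, 32, 35, 38, 41]
reference: FG1
kinases: [PKC, CK2]
freq_model: F3X4
K: 10
branch_mode: scale
include_stem: true
cleandata: true
alpha: 0.05
flank_window: 5
identity_floor: 30
seed: 1
out_dir: results/pipeline
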