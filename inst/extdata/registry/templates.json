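{
  "default": [
    "source name",
    "characteristics[organism]",
    "characteristics[organism part]",
    "characteristics[disease]",
    "characteristics[cell type]",
    "assay name",
    "comment[fraction identifier]",
    "comment[label]",
    "comment[data file]",
    "comment[instrument]",
    "comment[cleavage agent details]",
    "comment[modification parameters]",
    "technology type"
  ],
  "human": [
    "source name",
    "characteristics[organism]",
    "characteristics[organism part]",
    "characteristics[disease]",
    "characteristics[cell type]",
    "characteristics[ancestry category]",
    "characteristics[age]",
    "characteristics[sex]",
    "assay name",
    "comment[fraction identifier]",
    "comment[label]",
    "comment[data file]",
    "comment[instrument]",
    "comment[cleavage agent details]",
    "comment[modification parameters]",
    "technology type"
  ],
  "vertebrates": [
    "source name",
    "characteristics[organism]",
    "characteristics[organism part]",
    "characteristics[disease]",
    "characteristics[cell type]",
    "characteristics[developmental stage]",
    "assay name",
    "comment[fraction identifier]",
    "comment[label]",
    "comment[data file]",
    "comment[instrument]",
    "comment[cleavage agent details]",
    "comment[modification parameters]",
    "technology type"
  ],
  "invertebrates": [
    "source name",
    "characteristics[organism]",
    "characteristics[organism part]",
    "characteristics[disease]",
    "characteristics[cell type]",
    "characteristics[developmental stage]",
    "assay name",
    "comment[fraction identifier]",
    "comment[label]",
    "comment[data file]",
    "comment[instrument]",
    "comment[cleavage agent details]",
    "comment[modification parameters]",
    "technology type"
  ],
  "plants": [
    "source name",
    "characteristics[organism]",
    "characteristics[organism part]",
    "characteristics[disease]",
    "characteristics[cell type]",
    "assay name",
    "comment[fraction identifier]",
    "comment[label]",
    "comment[data file]",
    "comment[instrument]",
    "comment[cleavage agent details]",
    "comment[modification parameters]",
    "technology type"
  ],
  "cell-lines": [
    "source name",
    "characteristics[organism]",
    "characteristics[organism part]",
    "characteristics[disease]",
    "characteristics[cell type]",
    "characteristics[cell line]",
    "assay name",
    "comment[fraction identifier]",
    "comment[label]",
    "comment[data file]",
    "comment[instrument]",
    "comment[cleavage agent details]",
    "comment[modification parameters]",
    "technology type"
  ]
}
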