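{
  "description": "Required fields of a cnvtriage sample-report JSON.",
  "required_top": ["meta", "filtration", "cnvs"],
  "required_meta": ["package_version", "config_hash", "genome_build", "per_step_counts"],
  "required_cnv": ["row", "bundle"]
}
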