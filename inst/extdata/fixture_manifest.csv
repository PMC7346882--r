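"file","md5"
"config.yaml","bfd2c1e933a5d852dbe3ce17d3c2a18d"
"slide_truth.json","37d28af8f019bca5fcbecf0b54cfbaf9"
"study.csv","971aac9ba800a6011ad5195d7d29a00f"
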