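{
  "_comment": "Synthetic stand-in for the refseq_protein database metadata: sizes match the published figures (135 GB of files, ~96 GB needed in memory for an efficient search); sequence counts are plausible, not authoritative.",
  "name": "refseq_protein",
  "molecule": "protein",
  "num-letters": 90000000000,
  "num-sequences": 250000000,
  "total-bytes": 144955146240,
  "bytes-to-cache": 103079215104,
  "version": "1.0"
}
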