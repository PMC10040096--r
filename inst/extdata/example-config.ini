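# Example three-section run configuration (GCP, discounted instances).
# Every key can also be given as a command-line flag; flags win.

[cloud-provider]
provider = gcp
region = us-east4

[cluster]
num-nodes = 4
use-preemptible = yes

[blast]
program = blastx
db = refseq_protein.synthetic-metadata.json
queries = queries.fa
results = gs://my-bucket/results
options = -outfmt 7 -evalue 0.01 -task blastx-fast
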