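seed: 1
out: molembed_out/featurize
mode: 3D
'n': 32
epochs: 30
batch: 8
steps: 600
smiles-file: does/not/exist.smi
package_version: 0.1.0
r_version: R version 4.3.3 (2024-02-29)
config_hash: 9452
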