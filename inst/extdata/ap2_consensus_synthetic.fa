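>AP2_consensus_synthetic synthetic DREB-like AP2/ERF domain consensus (~58 aa); constructed in-package, not derived from any curated seed alignment
HYRGVRQRPWGKWVAEIRDPRKGVRVWLGTFDTAEEAARAYDVAALRFRGRKAKLNFP
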