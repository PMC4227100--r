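hsa-mir-130a, hsa-mir-222, hsa-mir-29a, hsa-mir-23a, hsa-mir-24-1, hsa-mir-24-2, hsa-mir-30a, hsa-mir-27a, hsa-mir-22, hsa-mir-100
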