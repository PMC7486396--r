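unit_id,aggregate_id
17031,chicago_msa
17043,chicago_msa
36061,newyork_msa
36103,newyork_msa
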