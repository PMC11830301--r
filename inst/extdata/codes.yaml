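# Default ICD-10 code sets for phenotype classification.
# "mdd" lists the non-psychotic depressive-episode sub-codes; psychotic MDD
# follows the F32.3/F33.3 convention. Both conventions for the psychotic /
# severe sub-codes are shipped; select the alternative explicitly if wanted.
psychotic_mdd: ["F32.3", "F33.3"]
psychotic_mdd_severe_incl: ["F32.2", "F32.3"]
mdd: ["F32.0", "F32.1", "F32.2", "F32.8", "F32.9",
      "F33.0", "F33.1", "F33.2", "F33.8", "F33.9"]
severe_non_psychotic_mdd: ["F32.2", "F33.2"]
bd: ["F30", "F31"]
scz_sad: ["F20", "F25"]
other_psychotic: ["F21", "F22", "F23", "F24", "F28", "F29"]
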