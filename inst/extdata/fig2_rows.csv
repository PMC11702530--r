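Kidney v1.5 extract,,,,,
AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID,AS/3/LABEL,AS/3/ID
kidney,UBERON:0002113,,,,
kidney,UBERON:0002113,renal papilla,UBERON:0001228,,
kidney,UBERON:0002113,nephron,UBERON:0001285,,
kidney,UBERON:0002113,nephron,UBERON:0001285,renal corpuscle,UBERON:0001229
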