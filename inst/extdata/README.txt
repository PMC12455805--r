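kegg_modules_snapshot.tsv
  Offline snapshot (flat TSV: module_id, definition, name, category) of the
  public KEGG MODULE DEFINITION strings for the two glycolysis modules
  M00001 and M00002, kept for tests and examples so no network access is
  needed. The transcription is validated arithmetically: the per-step
  option-count product of M00001 is 7*4*4*5*1*3*4*1*2 = 13,440 alternatives
  and of M00002 is 1*3*4*1*2 = 24, the known counts for these modules.
  Definitions evolve with KEGG releases; refresh with
  kegg_fetch_module_definition() when online.
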