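# Packaged data files

- `mechanical_axis.gmt` — the curated cytoskeletal–nuclear mechanical-axis
  gene set (55 genes: lamins, cytoskeletal actins, tubulin isoforms, the
  LINC complex, and the nuclear pore complex with associated transport
  factors). The named gene families are expanded to the standard human
  nucleoporin complement to reach the stated total; membership is a
  reconstruction, not a download from any database.
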