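ercc_latin_square_design.csv
----------------------------

Reconstructed modified Latin square design for the ERCC pool experiment
(Pools 12-15): 97 controls, one row each.

Columns
  control_id          ERCC identifier (ERCC-00001 .. ERCC-00176 namespace)
  subpool             A-E, or "omitted" (ERCC-00073, left out of all pools
                      so it can serve as a background probe on arrays)
  base_abundance      relative abundance in the subpool ladder (pool-12
                      units for subpool B; multiply by proportion/10 for a
                      pool's nominal value). 0 for the omitted control.
  antisense           TRUE for the seven controls transcribed antisense;
                      sense-strand probes/references yield no signal, so
                      these are excluded from analysis.
  non_srm             TRUE for ERCC-00114 only (not part of SRM 2374).
  reassigned_subpool  "C" for ERCC-00113 (signal pattern consistent with
                      subpool C membership, a subpool preparation error);
                      empty otherwise.

Ladder reconstruction notes: the published rendering of the design table is
typographically ambiguous. Each subpool's 19 SRM controls sit on the ladder
{2^0..2^16, 2^18, 2^20} (min-to-max span 2^20), paired to controls in the
printed order; the per-control log2 target abundances printed with the
outlier census confirm this pairing for every control that appears there.
The non-SRM ERCC-00114 occupies the 2^17 slot of subpool A, which is why
subpool A's printed value run shows 20 values {2^0..2^18, 2^20}.

Mixing proportions (percent by volume, pools 12,13,14,15):
  A: 10,10,10,10 (constant - the "modification")
  B: 10,15,25,40
  C: 15,25,40,10
  D: 25,40,10,15
  E: 40,10,15,25
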