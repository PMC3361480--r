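# dynfba native model format
metabolites
Ru5P x0=1 xmin=0 xmax=20 name="ribulose-5-phosphate"
RuBP x0=2 xmin=0 xmax=20 name="ribulose-1,5-bisphosphate"
PGA x0=2.4 xmin=0 xmax=20 name="3-phosphoglycerate"
DPGA x0=1 xmin=0 xmax=20 name="1,3-diphosphoglycerate"
GAP x0=1 xmin=0 xmax=20 name="glyceraldehyde-3-phosphate"
Sink x0=1 xmin=0 xmax=20 name="sink"
reactions
v1: RuBP -> 2 PGA vmin=0 vmax=3.78
v2: PGA -> DPGA vmin=0 vmax=11.75
v3: DPGA -> GAP vmin=0 vmax=5.04
v4: GAP -> 0.6 Ru5P vmin=0 vmax=3.05
v5: Ru5P -> RuBP vmin=0 vmax=8
v6: PGA -> Sink vmin=0 vmax=3
v7: GAP -> Sink vmin=0 vmax=0.1
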