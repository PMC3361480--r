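# dynfba native model format
metabolites
SugarP x0=0.5 xmin=0 xmax=20 name="sugar phosphates"
Sucrose x0=2 xmin=0 xmax=20 name="sucrose"
Glucose x0=1 xmin=0 xmax=20 name="glucose"
Fructose x0=1 xmin=0 xmax=20 name="fructose"
Starch x0=5 xmin=0 xmax=20 name="starch"
Sink x0=1 xmin=0 xmax=20 name="sink export"
reactions
photo: -> SugarP vmin=0 vmax=piecewise( 0:1,16:0)
suc_syn: 2 SugarP -> Sucrose vmin=0 vmax=1.5
sta_syn: SugarP -> Starch vmin=0 vmax=1
sta_deg: Starch -> SugarP vmin=0 vmax=0.6
invertase: Sucrose -> Glucose + Fructose vmin=0 vmax=1.2
hexokinase: Glucose + Fructose -> 2 SugarP vmin=0 vmax=1
export: Sucrose -> Sink vmin=0 vmax=0.8
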