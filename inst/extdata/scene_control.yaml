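# Simplified control synapse: 2 astrocytic sheets of 0.69 um^2 at 116 nm
worldEdge: 1.0
preVolume: 0.079
preRadius: 0.27
postVolume: 0.040
postRadius: 0.27
cleftHeight: 20
psdArea: 0.10
nAstro: 2
astroArea: 0.69
astroDistance: 116
transporterDensity: 10800
gluaPsdDensity: 200
glunPsdDensity: 300
gluaExtraDensity: 40
glunExtraDensity: 60
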