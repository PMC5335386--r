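# Simplified PAR1-activated (TFLLR) synapse: 4 sheets of 0.54 um^2 at 190 nm
worldEdge: 1.0
preVolume: 0.065
preRadius: 0.24
postVolume: 0.029
postRadius: 0.24
cleftHeight: 20
psdArea: 0.10
nAstro: 4
astroArea: 0.54
astroDistance: 190
transporterDensity: 10800
gluaPsdDensity: 200
glunPsdDensity: 300
gluaExtraDensity: 40
glunExtraDensity: 60
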