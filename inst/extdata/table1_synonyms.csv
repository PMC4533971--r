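raw,canonical
Nutrient inputs,nutrient inputs
Nutrient intputs,nutrient inputs
Climate change,climate change
Fertilizers use,fertilizers use
Fishing,fishing
Erosion,erosion
Deforestation,deforestation
Sediments,sediments
Aquaculture,aquaculture
Agriculture,agriculture
Ranching (livestock),ranching (livestock)
Sea surface temperature,sea surface temperature
Coastal erosion,coastal erosion
ENSO like events,enso like events
NSO like events,enso like events
upwelling,upwellings
green house gases,greenhouse gases
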