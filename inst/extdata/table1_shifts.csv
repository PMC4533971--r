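shift,ecosystem
Eutrophication,Aquatic-Coastal
Marine food web simplification,Aquatic-Coastal
Hypoxia,Aquatic-Coastal
Fisheries collapse,Aquatic-Marine
Floating plants,Aquatic
River channel change,Aquatic
Mangroves transitions,Aquatic-Coastal
Sea grass transitions,Aquatic-Coastal
Marine eutrophication,Marine
West Antarctica Ice Sheet collapse,Polar
Bivalves collapse,Marine
Coral transitions,Marine
Kelp transitions,Marine
Encroachment,Savannas
Soil salinization,Dry lands
Forest to savannas,Forest-Savanna
Dry land degradation,Dry lands
Tundra to forest,Tundra
Monsoon,Marine-Terrestrial
Peatlands,Peatlands
Greenland Ice Sheet melting,Polar
Thermohaline Circulation Collapse,Polar-Marine
Salt marshes to tidal flats,Marine-Coastal
Arctic Sea Ice collapse,Polar
Steppe to tundra,Steppe
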