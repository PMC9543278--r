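category_i,category_j,d
primary vegetation,mature secondary vegetation,0.30
primary vegetation,intermediate secondary vegetation,0.45
primary vegetation,young secondary vegetation,0.55
primary vegetation,plantation forest,0.60
primary vegetation,cropland,0.75
primary vegetation,pasture,0.70
primary vegetation,urban,0.85
mature secondary vegetation,intermediate secondary vegetation,0.25
mature secondary vegetation,young secondary vegetation,0.40
mature secondary vegetation,plantation forest,0.45
mature secondary vegetation,cropland,0.65
mature secondary vegetation,pasture,0.60
mature secondary vegetation,urban,0.80
intermediate secondary vegetation,young secondary vegetation,0.20
intermediate secondary vegetation,plantation forest,0.40
intermediate secondary vegetation,cropland,0.55
intermediate secondary vegetation,pasture,0.50
intermediate secondary vegetation,urban,0.70
young secondary vegetation,plantation forest,0.35
young secondary vegetation,cropland,0.45
young secondary vegetation,pasture,0.40
young secondary vegetation,urban,0.65
plantation forest,cropland,0.50
plantation forest,pasture,0.45
plantation forest,urban,0.60
cropland,pasture,0.30
cropland,urban,0.50
pasture,urban,0.55
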