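specimen,latitude,longitude,min_age,max_age,location,method
Vi-33-19,46.301562,16.079687,50901,45561,Box 1,Age at 68.3% probability
Vi-208,46.301562,16.079687,47256,44126,Box 1,Age at 68.3% probability
Vi-207,46.301562,16.079687,48904,44579,Box 1,Age at 68.3% probability
Mammoth from layer D - same layer as the discovered Neanderthals OxA-24944,50.366,19.294,52257,46646,Box 1,Age at 68.3% probability
Star 1,44.75,33.92,43858,42695,Box 2,Age at 68.3% probability
Mezmaiskaya 2,44.5540,39.5534,43986,42526,Box 2,Age at 68.3% probability
Chagyrskaya Level 6a where Neanderthal remains were found,51.263299,83.091628,53000,48200,Box 4,Weighted arithmetic mean age from four samples
Chagyrskaya Level 6b where Neanderthal remains were found,51.263299,83.091628,55000,49200,Box 4,Weighted arithmetic mean age from two samples
Chagyrskaya Level 6C where Neanderthal remains were found,51.263299,83.091628,57400,52400,Box 4,Weighted arithmetic mean age from nine samples
Layer 7 sediment where a Neanderthal was found,51.40,84.20,51338,44716,Box 4,Age at 68.3% probability
Layer 7 sediment where a Neanderthal was found,51.40,84.20,51903,44801,Box 4,Age at 68.3% probability
Denisova 11 age estimates,51.235,84.403,118100,79300,Box 4,
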