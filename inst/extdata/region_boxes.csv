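label,lon_min,lon_max,lat_min,lat_max
Box 1,12.5,21,44,53
Box 2,31,43.5,43.5,49
Box 4,80,89,47.5,53
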