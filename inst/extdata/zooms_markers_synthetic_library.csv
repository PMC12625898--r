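taxon,marker,mz
Hominidae,A,1235.71
Hominidae,B,1478.74
Hominidae,C,1580.86
Hominidae,D,2115.19
Hominidae,E,
Hominidae,F,2869.56
Hominidae,G,2957.68
Equus,A,1105.60
Equus,B,1427.72
Equus,C,1550.64
Equus,D,2129.19
Equus,E,2155.10
Equus,F,2849.53
Equus,G,2999.50
Bovidae,A,1192.61
Bovidae,B,1443.76
Bovidae,C,1601.85
Bovidae,D,2139.40
Bovidae,E,2183.20
Bovidae,F,2883.60
Bovidae,G,3017.30
Cervidae,A,1192.61
Cervidae,B,1443.76
Cervidae,C,1601.85
Cervidae,D,2139.40
Cervidae,E,2179.10
Cervidae,F,2899.70
Cervidae,G,3033.45
Canis lupus,A,1126.58
Canis lupus,B,1453.80
Canis lupus,C,1566.30
Canis lupus,D,2069.00
Canis lupus,E,2201.15
Canis lupus,F,2819.40
Canis lupus,G,2967.90
Rhinocerotidae,A,1141.55
Rhinocerotidae,B,1467.70
Rhinocerotidae,C,1614.77
Rhinocerotidae,D,2097.10
Rhinocerotidae,E,2219.30
Rhinocerotidae,F,2915.30
Rhinocerotidae,G,3059.20
Capra,A,1180.60
Capra,B,1439.70
Capra,C,1572.80
Capra,D,2147.30
Capra,E,2191.50
Capra,F,2833.20
Capra,G,2983.10
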