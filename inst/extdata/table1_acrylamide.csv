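category,n,mean,sd,median,p95,min,max
Biscuits,20,61,20,61,79,<LOQ,109
Ground biscuits,20,39,11,36,63,<LOQ,55
Multigrain meal,14,<LOD,,<LOD,<LOD,<LOD,<LOD
Sweet snacks,12,<LOQ,,<LOQ,<LOQ,<LOD,<LOQ
Savory snacks,12,<LOQ,,<LOQ,<LOQ,<LOQ,<LOQ
Plum puree,12,<LOQ,,<LOQ,32,<LOD,32
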