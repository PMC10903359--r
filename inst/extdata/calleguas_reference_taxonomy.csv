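taxon,class,order,family,genus,species
Fundulus lima,Actinopteri,Cyprinodontiformes,Fundulidae,Fundulus,Fundulus lima
Sardinops sagax,Actinopteri,Clupeiformes,Alosidae,Sardinops,Sardinops sagax
Bodianus pulcher,Actinopteri,Labriformes,Labridae,Bodianus,Bodianus pulcher
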