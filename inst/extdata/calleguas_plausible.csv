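taxon,class,order,family,genus,species,previously_reported,habitat,sequenced
Ameiurus nebulosus,Actinopteri,Siluriformes,Ictaluridae,Ameiurus,Ameiurus nebulosus,3,freshwater,TRUE
Atherinops affinis,Actinopteri,Atheriniformes,Atherinopsidae,Atherinops,Atherinops affinis,"1,4,5",estuarine,TRUE
Carassius auratus,Actinopteri,Cypriniformes,Cyprinidae,Carassius,Carassius auratus,3,estuarine,TRUE
Citharichthys stigmaeus,Actinopteri,Pleuronectiformes,Paralichthyidae,Citharichthys,Citharichthys stigmaeus,,estuarine,TRUE
Clevelandia ios,Actinopteri,Gobiiformes,Gobiidae,Clevelandia,Clevelandia ios,"1,4,5",estuarine,TRUE
Cottus asper,Actinopteri,Perciformes,Cottidae,Cottus,Cottus asper,2,freshwater,TRUE
Cymatogaster aggregata,Actinopteri,Perciformes,Embiotocidae,Cymatogaster,Cymatogaster aggregata,8,estuarine,TRUE
Cyprinus carpio,Actinopteri,Cypriniformes,Cyprinidae,Cyprinus,Cyprinus carpio,1,estuarine,TRUE
Engraulis mordax,Actinopteri,Clupeiformes,Engraulidae,Engraulis,Engraulis mordax,,marine,TRUE
Eucyclogobius newberryi,Actinopteri,Gobiiformes,Gobiidae,Eucyclogobius,Eucyclogobius newberryi,1,estuarine,TRUE
Fundulus parvipinnis,Actinopteri,Cyprinodontiformes,Fundulidae,Fundulus,Fundulus parvipinnis,1,estuarine,FALSE
Gambusia affinis,Actinopteri,Cyprinodontiformes,Poeciliidae,Gambusia,Gambusia affinis,"1,3,5",estuarine,TRUE
Gila orcuttii,Actinopteri,Cypriniformes,Leuciscidae,Gila,Gila orcuttii,3,freshwater,TRUE
Gillichthys mirabilis,Actinopteri,Gobiiformes,Gobiidae,Gillichthys,Gillichthys mirabilis,"1,5",estuarine,TRUE
Hypsopsetta guttulata,Actinopteri,Pleuronectiformes,Pleuronectidae,Hypsopsetta,Hypsopsetta guttulata,,estuarine,TRUE
Ilypnus gilberti,Actinopteri,Gobiiformes,Gobiidae,Ilypnus,Ilypnus gilberti,1,estuarine,FALSE
Lepomis cyanellus,Actinopteri,Perciformes,Centrarchidae,Lepomis,Lepomis cyanellus,5,freshwater,TRUE
Leptocottus armatus,Actinopteri,Perciformes,Cottidae,Leptocottus,Leptocottus armatus,"1,5",estuarine,TRUE
Leuresthes tenuis,Actinopteri,Atheriniformes,Atherinopsidae,Leuresthes,Leuresthes tenuis,,marine,TRUE
Micropterus salmoides,Actinopteri,Perciformes,Centrarchidae,Micropterus,Micropterus salmoides,3,freshwater,TRUE
Mugil cephalus,Actinopteri,Mugiliformes,Mugilidae,Mugil,Mugil cephalus,,estuarine,TRUE
Paralichthys californicus,Actinopteri,Pleuronectiformes,Paralichthyidae,Paralichthys,Paralichthys californicus,"1,4",estuarine,TRUE
Quietula y-cauda,Actinopteri,Gobiiformes,Gobiidae,Quietula,Quietula y-cauda,,estuarine,FALSE
Syngnathus leptorhynchus,Actinopteri,Syngnathiformes,Syngnathidae,Syngnathus,Syngnathus leptorhynchus,,estuarine,TRUE
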