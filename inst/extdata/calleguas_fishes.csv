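taxon,rank,exogenous,previous_refs,edna_reads,seine_count
Ameiurus nebulosus,species,FALSE,3,0,
Atherinops affinis,species,FALSE,"1,4,5",36158,159
Carassius auratus,species,FALSE,3,?,
Citharichthys stigmaeus,species,FALSE,,10,
Clevelandia ios,species,FALSE,"1,4,5",402,42
Cottus asper,species,FALSE,2,?,
Cymatogaster aggregata,species,FALSE,8,752,
Cyprinus carpio,species,FALSE,1,?,
Eucyclogobius newberryi,species,FALSE,1,0,
Fundulus parvipinnis,species,FALSE,1,110119,468
Gambusia affinis,species,FALSE,"1,3,5",304,
Gila orcuttii,species,FALSE,3,0,
Gillichthys mirabilis,species,FALSE,"1,5",384,1
Hypsopsetta guttulata,species,FALSE,,1491,
Ilypnus gilberti,species,FALSE,1,?,
Lepomis cyanellus,species,FALSE,5,0,
Leptocottus armatus,species,FALSE,"1,5",544,3
Micropterus salmoides,species,FALSE,3,29,
Mugil cephalus,species,FALSE,,19013,Visual
Paralichthys californicus,species,FALSE,"1,4",28,6
Quietula y-cauda,species,FALSE,,?,1
Syngnathus leptorhynchus,species,FALSE,,0,2
Gobiidae (Quietula y-cauda or Ilypnus gilberti),family,FALSE,,176,
Cypriniformes (Carassius auratus or Cyprinus carpio),order,FALSE,,312,
Engraulis mordax,species,TRUE,,14,
Leuresthes tenuis,species,TRUE,,192,
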