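mirna	species	orders
hsa-miR-1973	Hsa	Primates
hsa-miR-1275	Hsa,Ptr,Ppy	Primates
hsa-miR-494	Hsa,Ptr,Ppy,Mml,Mmu,Rno,Cfa,Eca,Bta,Ssc	Primates,Glires,Carnivora,Perissodactyla,Cetartiodactyla
hsa-miR-513a	Hsa,Ptr,Ppy,Mml,Age,Ssy,Pbi	Primates
hsa-miR-1246	Hsa,Ptr,Ppy	Primates
hsa-miR-328	Hsa,Ptr,Ppy,Mmu,Rno,Cfa,Eca,Bta,Ssc	Primates,Glires,Carnivora,Perissodactyla,Cetartiodactyla
hsa-miR-1908	Hsa,Ppy	Primates
hsa-miR-1972	Hsa	Primates
hsa-miR-1974	Hsa	Primates
hsa-miR-1977	Hsa	Primates
hsa-miR-638	Hsa,Ppy,Mml	Primates
hsa-miR-1978	Hsa	Primates
hsa-miR-1201	Hsa,Ptr,Ppy	Primates
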