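(Amborella,((Trithuria,((Cabomba,Brasenia),(Nuphar,(Nymphaea,Victoria)))),((Austrobaileya,Schisandra),(((Hedyosmum,(Ascarina,(Sarcandra,Chloranthus))),Ceratophyllum),(((Magnolia,Liriodendron),((Laurus,Annona),(Piper,Asarum))),((Acorus,(((Arum,Spathiphyllum),(Tofieldia,(Alisma,Butomus))),(Lilium,Oryza))),((Euptelea,(Papaver,(Ranunculus,Berberis))),(Platanus,((Arabidopsis,Citrus),(Vitis,(Asclepias,Helianthus)))))))))));
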